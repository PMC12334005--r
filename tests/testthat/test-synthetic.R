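test_that("trigonometric parameters satisfy zero-sum via the intercept correction", {
  g <- apc_grid(10, 10)
  tp <- make_trig_params(g, slopes = c(0.1, -0.1, 0.1),
                         amps = c(0.05, -0.05, 0.05))
  # even block length: cos correction vanishes
  expect_equal(tp$intercepts[1:2], c(0, 0))
  # odd cohort block (K = 19): correction amp / K
  expect_equal(tp$intercepts[3], 0.05 / 19)
  expect_equal(sum(tp$betaA), 0, tolerance = 1e-12)
  expect_equal(sum(tp$betaP), 0, tolerance = 1e-12)
  expect_equal(sum(tp$betaC), 0, tolerance = 1e-12)

  zero <- make_trig_params(g)
  expect_equal(zero$betaA, rep(0, 10))
  expect_equal(zero$betaC, rep(0, 19))

  # realized block = intercept + slope * v + amp * (-1)^m
  m <- seq_len(19)
  expect_equal(tp$betaC,
               0.05 / 19 + 0.1 * centered_index(19) + 0.05 * (-1)^m)
})

test_that("decomposing realized blocks returns slopes up to the cosine leakage bound", {
  g <- apc_grid(10, 11)   # K = 20 even, J = 11 odd: both parities covered
  tp <- make_trig_params(g, slopes = c(0.07, -0.02, 0.12),
                         amps = c(0.05, 0.04, -0.03))
  blocks <- list(tp$betaA, tp$betaP, tp$betaC)
  lens <- c(g$I, g$J, g$K)
  for (b in 1:3) {
    v <- centered_index(lens[b])
    leak <- abs(tp$amps[b]) * abs(sum(v * (-1)^seq_len(lens[b]))) / sum(v^2)
    got <- decompose(blocks[[b]], v)$slope
    expect_lte(abs(got - tp$slopes[b]), leak + 1e-12)
  }
  # even-length blocks still leak: cos(pi*i) is not index-orthogonal there
  expect_gt(abs(decompose(tp$betaA)$slope - tp$slopes[1]), 1e-4)
})

test_that("generated data equal cell sums in the noise-free limit and obey N = I*J*r", {
  g <- apc_grid(10, 10)
  tp0 <- make_trig_params(g, c(0.1, 0, -0.1), c(0.05, 0.02, 0), gamma = 0)
  d0 <- generate_data(tp0, 10, seed = 5)
  expect_equal(nrow(d0), 1000L)
  expect_equal(d0$y, cell_means(as_effect_set(tp0), d0))

  # determinism and per-cell law of large numbers
  tp <- make_trig_params(g, c(0, 0, 0.1), c(0, 0, 0.05), gamma = 0.1)
  d1 <- generate_data(tp, 10, seed = 9)
  expect_identical(generate_data(tp, 10, seed = 9)$y, d1$y)
  expect_false(identical(generate_data(tp, 10, seed = 10)$y, d1$y))

  many <- generate_data(tp, 400, seed = 11)
  cellbar <- tapply(many$y, list(many$i, many$j), mean)
  truthmat <- tapply(cell_means(as_effect_set(tp), many),
                     list(many$i, many$j), mean)
  expect_lt(max(abs(cellbar - truthmat)), 4 * 0.1 / sqrt(400))
})

test_that("the systematic design enumerates exactly the 13 canonical sign cases", {
  cases <- enumerate_sim1_cases()
  expect_equal(nrow(cases), 13L)
  expect_equal(cases$case, 1:13)

  # case 3: cohort-only positive pattern
  expect_equal(unlist(cases[3, c("A", "P", "C")], use.names = FALSE),
               c("0", "0", "+"))
  expect_equal(cases$slopeC[3], 0.1)
  expect_equal(cases$ampC[3], 0.05)
  expect_equal(cases$slopeA[3], 0)

  # case 13: the fully canceling pattern
  expect_equal(unlist(cases[13, c("A", "P", "C")], use.names = FALSE),
               c("+", "-", "+"))

  key <- apply(cases[c("A", "P", "C")], 1, paste, collapse = "")
  expect_false("000" %in% key)
  flip <- chartr("+-", "-+", key)
  expect_length(intersect(key, flip), 0)   # no global sign-flip pairs
  expect_length(unique(key), 13L)
  # magnitudes always paired: slope 0.1 with amp 0.05, same sign
  expect_equal(as.matrix(cases[, 8:10]),
               0.5 * as.matrix(cases[, 5:7]), ignore_attr = TRUE)
})

test_that("randomized component draws have the stated scales and coupling", {
  # marginal scale: variance 0.1 for every Sim-2 amount
  draws2 <- vapply(1:4000, function(t) unlist(draw_sim2(t)[c("slopes", "amps")]),
                   numeric(6))
  expect_equal(mean(draws2), 0, tolerance = 0.005)
  expect_equal(sd(as.vector(draws2)), sqrt(0.1), tolerance = 0.01)
  expect_identical(draw_sim2(123)$slopes, draw_sim2(123)$slopes)

  # Sim 3: slopes shrink with their own amplitude, E[slope^2 | amp] = amp^2
  draws3 <- lapply(1:4000, draw_sim3)
  amps <- t(vapply(draws3, `[[`, numeric(3), "amps"))
  slopes <- t(vapply(draws3, `[[`, numeric(3), "slopes"))
  expect_equal(sd(as.vector(amps)), sqrt(0.1), tolerance = 0.01)
  ratio <- as.vector(slopes / amps)   # standard normal if coupling holds
  expect_equal(mean(ratio^2), 1, tolerance = 0.05)
  expect_equal(mean(ratio), 0, tolerance = 0.03)

  # no draw falls in the near-pure-linear gray region off the axis
  expect_false(any(abs(amps) <= 0.2 * abs(slopes) & slopes != 0))

  # literal coupling ties every slope's scale to the age amplitude
  lit <- lapply(1:2000, draw_sim3, literal = TRUE)
  la <- t(vapply(lit, `[[`, numeric(3), "amps"))
  ls <- t(vapply(lit, `[[`, numeric(3), "slopes"))
  expect_equal(mean((ls[, 2] / la[, 1])^2), 1, tolerance = 0.1)
})

test_that("polynomial effects standardize powers and split linear from nonlinear", {
  # degree 1 is a pure rescaled index: no nonlinear component at all
  p1 <- polynomial_params(10, 1, seed = 81)
  expect_equal(p1$SD_NL, 0, tolerance = 1e-12)
  expect_equal(p1$eta_NL, rep(0, 10), tolerance = 1e-12)

  p <- polynomial_params(20, 8, seed = 82)
  expect_equal(colMeans(p$z), rep(0, 8), tolerance = 1e-12)
  expect_equal(apply(p$z, 2, function(x) sqrt(mean(x^2))), rep(1, 8))

  # slope equals an independent least-squares oracle; reconstruction holds
  v <- centered_index(20)
  expect_equal(p$eta_L, unname(coef(lm(p$eta ~ v))["v"]))
  expect_equal(p$eta_L * v + p$eta_NL, p$eta)
  expect_equal(sum(p$eta), 0, tolerance = 1e-12)

  expect_error(polynomial_params(2, 3), "integer >= 3")
})

test_that("low-degree polynomials often land near pure-linear, high-degree never do", {
  in_gray <- function(H) {
    hits <- 0L
    for (t in 1:300) {
      p <- polynomial_params(20, H, seed = 9000 + t)
      if (p$SD_NL <= 0.5 * abs(p$eta_L)) hits <- hits + 1L
    }
    hits
  }
  # at H = 2 the gray-region probability is ~5% (a Cauchy band in w2/w1),
  # so 300 draws give a clearly nonzero count; at H = 8 the odd powers make
  # a vanishing nonlinear part essentially impossible
  expect_gt(in_gray(2), 5L)
  expect_equal(in_gray(8), 0L)
})

test_that("parameter specifications round-trip through JSON", {
  g <- apc_grid(10, 10)
  tp <- make_trig_params(g, c(0.1, 0, -0.1), c(0.05, 0.02, 0), gamma = 0.2)
  tp2 <- params_from_json(params_to_json(tp))
  expect_equal(tp2$betaC, tp$betaC)
  expect_equal(tp2$gamma, 0.2)
  expect_equal(tp2$grid$K, 19)

  cd <- draw_sim3(99)
  cd2 <- params_from_json(params_to_json(cd))
  expect_equal(cd2$slopes, cd$slopes)
  expect_s3_class(cd2, "apc_component_draw")
})
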