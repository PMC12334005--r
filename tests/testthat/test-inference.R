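# Sampler unit tests run on a reduced 6 x 6 grid with short chains so the
# whole file stays fast; full-scale sampler behavior is exercised by the
# acceptance tests.

short_config <- function(seed = 1) {
  sampler_config(chains = 4, iterations = 600, warmup = 200, thin = 2,
                 seed = seed)
}

test_that("split R-hat separates mixed from unmixed chains", {
  set.seed(51)
  mixed <- matrix(rnorm(4000), ncol = 4)
  expect_lt(rhat(mixed), 1.01)

  shifted <- mixed + rep(c(0, 5, 10, 15), each = 1000)
  expect_gt(rhat(shifted), 1.05)

  expect_equal(rhat(matrix(3.7, nrow = 100, ncol = 4)), 1)  # constant draws
  expect_error(rhat(matrix(rnorm(100), ncol = 1)), "2 chains")

  # a within-chain trend (first half differs from second) is also flagged
  trending <- matrix(rep(c(0, 4), each = 500) + rnorm(4000), ncol = 4)
  expect_gt(rhat(trending), 1.05)
})

test_that("check_convergence applies the 1.05 threshold to all parameters", {
  expect_true(check_convergence(c(a = 1.02, b = 1.01)))
  expect_false(check_convergence(c(a = 1.02, b = 1.06)))
  expect_error(check_convergence(numeric(0)), "no R-hat")
})

test_that("fits are deterministic given the seed and expose pooled medians", {
  td <- tiny_dataset(seed = 61, slopes = c(0.1, 0, 0), amps = c(0.05, 0, 0))
  f1 <- fit_apc("ridge", td$data, short_config(seed = 9))
  f2 <- fit_apc("ridge", td$data, short_config(seed = 9))
  expect_identical(f1$medians, f2$medians)
  expect_identical(f1$draws, f2$draws)

  # medians match a sort-based oracle on the pooled draws
  pooled <- f1$draws[, "bC[3]"]
  srt <- sort(pooled)
  n <- length(srt)
  oracle <- if (n %% 2 == 1) srt[(n + 1) / 2] else mean(srt[n / 2 + 0:1])
  expect_equal(unname(f1$medians["bC[3]"]), oracle)

  # retained draw count: chains x (iterations - warmup) / thin
  expect_equal(nrow(f1$draws), 4 * 200)
})

test_that("point estimates form a sum-to-zero effect set on the data's grid", {
  td <- tiny_dataset(seed = 62)
  f <- fit_apc("random_walk", td$data, short_config(seed = 3))
  pe <- point_estimates(f)
  expect_s3_class(pe, "effect_set")
  expect_equal(sum(pe$bA), 0, tolerance = 1e-12)
  expect_equal(sum(pe$bC), 0, tolerance = 1e-12)
  expect_equal(pe$grid$K, 11)
})

test_that("recorded log-posterior values agree with the printed-form evaluations", {
  td <- tiny_dataset(seed = 63, slopes = c(0, 0.1, 0), amps = c(0, 0.05, 0))
  for (kind in apc_model_kinds()) {
    f <- fit_apc(kind, td$data, short_config(seed = 17))
    rows <- c(1L, 57L, nrow(f$draws))
    g <- f$grid
    for (r in rows) {
      dr <- f$draws[r, ]
      e <- effect_set(dr[["b0"]],
                      dr[sprintf("bA[%d]", seq_len(g$I))],
                      dr[sprintf("bP[%d]", seq_len(g$J))],
                      dr[sprintf("bC[%d]", seq_len(g$K))],
                      grid = g, tol = 1e-6)
      sc <- if (kind == "ridge")
        scale_params(sigma = dr[["sigma"]], sigmaA = dr[["lambda"]])
      else
        scale_params(sigma = dr[["sigma"]], sigmaA = dr[["sigmaA"]],
                     sigmaP = dr[["sigmaP"]], sigmaC = dr[["sigmaC"]])
      expect_equal(log_posterior(kind, e, sc, td$data), dr[["lp__"]],
                   tolerance = 1e-6)
    }
  }
})

test_that("posterior medians recover matched data-generating shapes", {
  # random-walk prior on data whose cohort block carries the only slope
  g <- apc_grid(10, 10)
  truth <- make_trig_params(g, c(0, 0, 0.1), c(0, 0, 0.05), gamma = 0.1)
  d <- generate_data(truth, 10, seed = 71)
  f <- fit_apc("random_walk", d, sampler_config(seed = 72))
  expect_true(f$converged)
  s <- solve_s(point_estimates(f), truth)
  expect_lt(abs(s), 0.02)

  # intercept and noise scale are recovered too
  expect_lt(abs(f$medians[["b0"]]), 0.05)
  expect_lt(abs(f$medians[["sigma"]] - 0.1), 0.02)
})

test_that("invalid sampler configurations and degenerate data are rejected", {
  expect_error(sampler_config(warmup = 2000, iterations = 2000), "warmup")
  expect_error(sampler_config(chains = 0), "integer")
  td <- tiny_dataset(seed = 64)
  empty <- td$data[0, ]
  expect_error(fit_apc("ridge", apcbayes::apc_data(empty, attr(td$data, "grid")),
                       short_config()), "nonempty")
  skel <- expand_design(apc_grid(3, 3), 1)   # y unset
  expect_error(fit_apc("ridge", skel, short_config()), "nonempty|observed")
})

test_that("fit summaries serialize to JSON and draws to long CSV", {
  td <- tiny_dataset(seed = 65)
  f <- fit_apc("random_effects", td$data, short_config(seed = 5))
  js <- jsonlite::fromJSON(fit_to_json(f))
  expect_equal(js$kind, "random_effects")
  expect_equal(js$grid$K, 11)
  expect_equal(js$medians$sigma, unname(f$medians[["sigma"]]))
  expect_type(js$converged, "logical")

  path <- withr::local_tempfile(fileext = ".csv")
  write_draws_csv(f, path)
  long <- read.csv(path)
  expect_setequal(unique(long$parameter), setdiff(colnames(f$draws), "lp__"))
  expect_equal(nrow(long), nrow(f$draws) * (ncol(f$draws) - 1))
  got <- long$value[long$parameter == "sigma" & long$chain == 2]
  expect_equal(got, unname(f$draws[f$chain == 2, "sigma"]))
})
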