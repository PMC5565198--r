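test_that("SDT measures follow the normal-quantile definitions", {
  expect_equal(sdt_from_rates(0.7, 0.7, 100, 100)$dprime, 0)
  r <- sdt_from_rates(0.84, 0.16, 1000, 1000)
  expect_equal(r$dprime, 2 * qnorm(0.84), tolerance = 1e-12)
  expect_equal(r$criterion, 0)
  ## symmetric rates give zero criterion for any hit rate
  for (H in c(0.6, 0.75, 0.9))
    expect_equal(sdt_from_rates(H, 1 - H, 500, 500)$criterion, 0,
                 tolerance = 1e-12)
  ## perfect rates are clipped to 1/(2N)
  p <- sdt_from_rates(1, 0, 50, 50)
  expect_true(is.finite(p$dprime))
  expect_equal(p$h, 1 - 1 / 100)

  tr <- data.frame(q = c(1, 1, 0, 0),
                   response = c("congruent", "congruent", "incongruent",
                                "congruent"))
  expect_equal(compute_sdt(tr)$h, 1 - 1 / 4)
  expect_error(compute_sdt(data.frame(q = c(1, 1),
                                      response = c("congruent", "congruent"))),
               class = "sceneprobe_input_error")
})

test_that("log-ratios use natural log and exclude non-positive sensitivities", {
  expect_equal(log_ratio(1.5, 1.5), 0)
  expect_equal(log_ratio(2, 1), log(2))
  expect_true(is.na(log_ratio(1.2, 0)))
  expect_true(is.na(log_ratio(-0.1, 1)))
  expect_equal(log_ratio(c(2, 1), c(1, -1)), c(log(2), NA))
})

test_that("reverse correlation equals the direct four-class formula", {
  set.seed(61)
  noise <- matrix(runif(4 * 16, 0, 0.06), 4, 16)
  tr <- toy_trials(q = c(1, 0, 1, 0), z = c(1, 0, 0, 1), noise)
  tf <- reverse_correlation(tr)
  direct <- noise[1, ] + noise[2, ] - noise[3, ] - noise[4, ]
  expect_equal(tf$p, direct, tolerance = 1e-14)

  expect_error(reverse_correlation(toy_trials(c(1, 1, 0), c(1, 0, 1),
                                              noise[1:3, ])),
               class = "sceneprobe_estimation_error")
})

test_that("reverse correlation is linear in the noise and null-calibrated", {
  set.seed(62)
  n <- 20000
  noise <- matrix(rnorm(n * 16, 0.03, 0.007), n, 16)
  q <- rep(c(1L, 0L), n / 2)
  z <- sample(0:1, n, replace = TRUE)  # responses independent of the noise
  tr <- toy_trials(q, z, noise)
  tf <- reverse_correlation(tr)
  expect_true(all(abs(tf$p) < 3 * tf$se))

  tr2 <- toy_trials(q, z, 2.5 * noise)
  expect_equal(reverse_correlation(tr2)$p, 2.5 * tf$p, tolerance = 1e-12)
})

test_that("simulated template observers yield recoverable kernels", {
  w <- sceneprobe:::state_template(1.5)
  sig <- sceneprobe:::template_sigma_int(w, 0.12, 0.007, 2)
  tt <- template_trial_table(20000, w, sigma_int = sig, seed = 63)
  tf <- symmetrize(reverse_correlation(tt))
  expect_gte(cor(tf$p, w), 0.95)
})

test_that("symmetrization mirrors about the congruent/incongruent channels", {
  perm <- sceneprobe:::mirror_perm()
  sym <- symmetrize(1:16)
  expect_equal(sym, (1:16 + (1:16)[perm]) / 2)
  expect_equal(symmetrize(sym), sym)            # idempotent
  expect_equal(sym, sym[perm])                  # mirror invariant

  ## already-symmetric vector is a fixed point
  v <- rep(1, 16); v[5] <- 3; v[13] <- -2
  expect_equal(symmetrize(v), v)

  ## purely antisymmetric component flattens to its mean
  a <- numeric(16); a[4] <- 1; a[6] <- -1
  expect_equal(symmetrize(a), numeric(16))
})

test_that("retuning index follows the printed formula and is scale invariant", {
  p <- numeric(16); p[5] <- 1
  expect_equal(retuning_index(p), 1)
  p2 <- numeric(16); p2[5] <- 2; p2[13] <- -1
  expect_equal(retuning_index(p2), 1.8)
  expect_equal(retuning_index(0.3 * p2), 1.8, tolerance = 1e-12)
  peq <- rep(0.5, 16)
  expect_equal(retuning_index(peq), 0)
  expect_error(retuning_index(numeric(16)),
               class = "sceneprobe_undefined_value")
})

test_that("internal-noise inversion handles the boundary cases", {
  est0 <- estimate_internal_noise(0.75, 1)
  expect_identical(est0$sigma_int, 0)
  expect_true(est0$converged)

  ## stimulus-independent responding: sigma unbounded, flagged
  est_inf <- estimate_internal_noise(0.5, 0.5)
  expect_false(est_inf$converged)

  expect_error(estimate_internal_noise(1.2, 0.8),
               class = "sceneprobe_input_error")
})

test_that("internal-noise inversion recovers the forward model", {
  for (sig in c(0.6, 1.2)) {
    dp <- simulate_double_pass(10000, mu = 1.5, sigma_int = sig,
                               criterion = 0.2, seed = 71)
    est <- estimate_internal_noise(dp$pc, dp$pa, dp$p_yes)
    expect_equal(est$sigma_int, sig, tolerance = 0.2 * sig)
    expect_true(est$converged)
  }
  ## unbiased variant: criterion halfway between the classes, p_yes omitted
  dp <- simulate_double_pass(10000, mu = 1.5, sigma_int = 1,
                             criterion = 0.75, seed = 72)
  est <- estimate_internal_noise(dp$pc, dp$pa)
  expect_equal(est$sigma_int, 1, tolerance = 0.2)
})

test_that("median split labels strictly above the median as rich", {
  expect_equal(median_split_labels(c(1, 2, 3, 4)),
               c("poor", "poor", "rich", "rich"))
  expect_equal(median_split_labels(rep(2, 5)), rep("poor", 5))
  set.seed(73)
  for (i in 1:20) {
    v <- rnorm(sample(2:15, 1))
    lab <- median_split_labels(v)
    expect_lte(sum(lab == "rich"), floor(length(v) / 2))
    expect_equal(lab == "rich", v > sort(v)[ceiling(length(v) / 2)] |
                   v > stats::median(v))
  }
})

test_that("experiment summary composes per-cell SDT and calibrates under the null", {
  ## compositionality on a hand-built table
  set.seed(74)
  cells <- expand.grid(td = c("rich", "poor"), bu = c("rich", "poor"),
                       stringsAsFactors = FALSE)
  tr <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    n <- 200
    q <- rep(c(1, 0), n / 2)
    h <- 0.6 + 0.05 * i
    resp <- ifelse(q == 1, ifelse(runif(n) < h, "congruent", "incongruent"),
                   ifelse(runif(n) < 0.3, "congruent", "incongruent"))
    data.frame(observer_id = 1, td_label = cells$td[i], bu_label = cells$bu[i],
               q = q, response = resp)
  }))
  s <- summarize_experiment(tr)
  for (i in seq_len(nrow(cells))) {
    sub <- tr[tr$td_label == cells$td[i] & tr$bu_label == cells$bu[i], ]
    col <- sprintf("d_td_%s_bu_%s", cells$td[i], cells$bu[i])
    expect_equal(s$observers[[col]], compute_sdt(sub)$dprime)
  }

  ## null cohorts: no built-in rich/poor difference
  pvals <- sapply(1:20, function(r) {
    trn <- simulate_experiment(cohort = cohort_config(n_subjects = 8,
                                                      trials_per_cell = 100,
                                                      rich_axis = "none"),
                               seed = 200 + r)
    sn <- summarize_experiment(trn)
    c(sn$td$p, sn$bu$p, sn$td$ci, sn$bu$ci)
  })
  expect_gte(mean(pvals[1, ] > 0.05), 0.9)
  expect_gte(mean(pvals[2, ] > 0.05), 0.9)
  ## group median log-ratios near zero: CIs cover 0 most of the time
  covers_td <- pvals[3, ] <= 0 & pvals[4, ] >= 0
  expect_gte(mean(covers_td), 0.9)
})
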