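## -------------------------------------------------------------------------
## d'/criterion, rich/poor log-ratios, reverse-correlation tuning functions,
## retuning index, and double-pass internal-noise estimation.
## -------------------------------------------------------------------------

#' Signal detection measures from trial records
#'
#' Hit rate H = P(respond congruent | q = 1) and false-alarm rate
#' F = P(respond congruent | q = 0) are clipped to
#' \code{[1/(2N), 1 - 1/(2N)]} per class before the normal-quantile
#' transform; \code{d' = z(H) - z(F)}, \code{c = -(z(H) + z(F)) / 2}.
#'
#' @param trials data.frame with columns \code{q} (0/1) and \code{response}
#'   ("congruent"/"incongruent").
#' @return object of class \code{sdt_result}: dprime, criterion, h, f,
#'   n_signal, n_noise.
#' @export
compute_sdt <- function(trials) {
  if (!all(c("q", "response") %in% names(trials)))
    sp_input_error("trials must have columns q and response")
  n1 <- sum(trials$q == 1); n0 <- sum(trials$q == 0)
  if (n1 == 0 || n0 == 0)
    sp_input_error("both signal classes must be present")
  H <- mean(trials$response[trials$q == 1] == "congruent")
  F <- mean(trials$response[trials$q == 0] == "congruent")
  sdt_from_rates(H, F, n1, n0)
}

#' @rdname compute_sdt
#' @param H,F hit and false-alarm rates.
#' @param n_signal,n_noise trial counts behind each rate.
#' @export
sdt_from_rates <- function(H, F, n_signal, n_noise) {
  clip <- function(p, n) pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  Hc <- clip(H, n_signal); Fc <- clip(F, n_noise)
  zH <- stats::qnorm(Hc); zF <- stats::qnorm(Fc)
  structure(list(dprime = zH - zF, criterion = -(zH + zF) / 2,
                 h = Hc, f = Fc, n_signal = n_signal, n_noise = n_noise),
            class = "sdt_result")
}

#' @export
print.sdt_result <- function(x, ...) {
  cat(sprintf("<sdt_result> d'=%.4f c=%.4f (H=%.3f F=%.3f; n=%d/%d)\n",
              x$dprime, x$criterion, x$h, x$f, x$n_signal, x$n_noise))
  invisible(x)
}

#' Rich/poor sensitivity log-ratio
#'
#' Natural log of \code{d_rich / d_poor}. Estimates with either d' <= 0 are
#' excluded (returned as NA), matching the exclusion rule applied to
#' conditions where above-chance performance was not attained.
#'
#' @param d_rich,d_poor sensitivities (numeric, vectorized).
#' @return numeric; NA marks an excluded ratio.
#' @export
log_ratio <- function(d_rich, d_poor) {
  n <- max(length(d_rich), length(d_poor))
  d_rich <- rep_len(d_rich, n)
  d_poor <- rep_len(d_poor, n)
  out <- rep(NA_real_, n)
  ok <- d_rich > 0 & d_poor > 0
  out[ok] <- log(d_rich[ok] / d_poor[ok])
  out
}

noise_matrix <- function(trials) {
  cols <- sprintf("n%02d", 1:16)
  if (!all(cols %in% names(trials)))
    sp_input_error("trials must carry noise columns n01..n16")
  as.matrix(trials[, cols])
}

#' Reverse-correlation tuning function
#'
#' Combines the class-conditional noise averages
#' \code{p = <n[1,1]> + <n[0,0]> - <n[1,0]> - <n[0,1]>}, where n[q,z] is the
#' 16-entry noise vector of trials with signal class q and accuracy z and
#' <.> averages across trials of that class. Standard errors propagate the
#' four per-class variances.
#'
#' @param trials data.frame with columns q, z and n01..n16.
#' @return object of class \code{tuning_function}: p, se, n_class.
#' @export
reverse_correlation <- function(trials) {
  N <- noise_matrix(trials)
  classes <- list(c(1, 1), c(0, 0), c(1, 0), c(0, 1))
  signs <- c(1, 1, -1, -1)
  p <- numeric(16); v <- numeric(16); n_class <- integer(4)
  for (i in 1:4) {
    sel <- trials$q == classes[[i]][1] & trials$z == classes[[i]][2]
    n_class[i] <- sum(sel)
    if (n_class[i] == 0)
      sp_estimation_error(sprintf("empty class (q=%d, z=%d)",
                                  classes[[i]][1], classes[[i]][2]))
    p <- p + signs[i] * unname(colMeans(N[sel, , drop = FALSE]))
    v <- v + unname(apply(N[sel, , drop = FALSE], 2, stats::var)) / n_class[i]
  }
  names(n_class) <- c("q1z1", "q0z0", "q1z0", "q0z1")
  structure(list(p = p, se = sqrt(v), n_class = n_class),
            class = "tuning_function")
}

#' @export
print.tuning_function <- function(x, ...) {
  cat("<tuning_function> (channels 1-16; 5 congruent, 13 incongruent)\n")
  print(round(x$p, 5))
  invisible(x)
}

#' @export
plot.tuning_function <- function(x, ...) {
  graphics::plot(1:16, x$p, type = "b", xlab = "orientation channel",
                 ylab = "perceptual weight p", ...)
  graphics::arrows(1:16, x$p - x$se, 1:16, x$p + x$se, angle = 90,
                   code = 3, length = 0.03)
  graphics::abline(v = c(5, 13), lty = 3)
  invisible(x)
}

## mirror permutation about channels 5 and 13
mirror_perm <- function() ((9 - (1:16)) %% 16) + 1

#' Symmetrize a tuning function
#'
#' Averages entries equidistant clockwise/counterclockwise from the
#' congruent (5) and incongruent (13) channels. Idempotent.
#'
#' @param p 16-entry numeric vector or a \code{tuning_function}.
#' @return same type as the input.
#' @export
symmetrize <- function(p) {
  if (inherits(p, "tuning_function")) {
    p$p <- symmetrize(p$p)
    p$se <- sqrt((p$se^2 + p$se[mirror_perm()]^2)) / 2
    return(p)
  }
  if (length(p) != 16) sp_input_error("p must have 16 entries")
  (p + p[mirror_perm()]) / 2
}

#' Retuning index
#'
#' Squared congruent-incongruent difference of the tuning function,
#' normalized by its total energy: \code{(p[13] - p[5])^2 / sum(p^2)}.
#' Non-negative, enabling log-ratio computation.
#'
#' @param p 16-entry numeric vector or \code{tuning_function}.
#' @return numeric >= 0.
#' @export
retuning_index <- function(p) {
  if (inherits(p, "tuning_function")) p <- p$p
  if (length(p) != 16) sp_input_error("p must have 16 entries")
  tot <- sum(p^2)
  if (tot == 0) sp_undefined_value("zero tuning function: index undefined")
  (p[13] - p[5])^2 / tot
}

## ---- double-pass internal noise ------------------------------------------

## P(respond yes | external value e) under late noise sigma and criterion c
p_yes_given_e <- function(e, c, sigma) {
  if (sigma <= 0) return(as.numeric(e > c))
  stats::pnorm((e - c) / sigma)
}

## model-predicted percent agreement: external decision variable is a
## half/half mixture N(0,1) / N(mu,1); two passes share e, internal noise
## independent across passes
model_pa <- function(mu, c, sigma, n_grid = 2001) {
  if (sigma <= 0) return(1)
  integrate_comp <- function(m) {
    x <- seq(-8, 8, length.out = n_grid)
    w <- stats::dnorm(x)
    w <- w / sum(w)
    p <- p_yes_given_e(m + x, c, sigma)
    sum(w * (p^2 + (1 - p)^2))
  }
  0.5 * integrate_comp(0) + 0.5 * integrate_comp(mu)
}

## solve (mu, c) from observed (pc, p_yes) given total late-noise scale s:
## H = pc + p_yes - 1/2, F = p_yes - pc + 1/2 (exact algebra of the
## yes/no model); unbiased case (p_yes = NULL) sets c = mu/2
solve_mu_c <- function(pc, p_yes, s) {
  if (is.null(p_yes)) {
    mu <- 2 * s * stats::qnorm(pc)
    return(list(mu = mu, c = mu / 2))
  }
  H <- pc + p_yes - 0.5
  F <- p_yes - pc + 0.5
  if (H <= 0 || H >= 1 || F <= 0 || F >= 1) return(NULL)
  c <- s * stats::qnorm(1 - F)
  mu <- c - s * stats::qnorm(1 - H)
  list(mu = mu, c = c)
}

#' Estimate internal noise from double-pass statistics
#'
#' Inverts the two-pass late-noise SDT model: the external decision variable
#' (unit SD) is shared between passes, internal Gaussian noise of SD
#' \code{sigma_int} (in external-SD units) is drawn independently per pass,
#' and a fixed criterion produces yes/no responses. For each candidate
#' \code{sigma_int}, the signal separation and criterion are solved exactly
#' from percent correct (and the observed yes-rate, when given; otherwise an
#' unbiased criterion is assumed), and the predicted percent agreement is
#' computed by numerical integration; \code{sigma_int} minimizing the
#' squared agreement mismatch is returned. \code{pa = 1} yields exactly 0.
#'
#' @param pc percent correct, in (0, 1).
#' @param pa percent agreement across the two passes, in (0, 1].
#' @param p_yes optional observed proportion of "congruent" responses
#'   (pins down the response bias).
#' @param sigma_max upper search bound (default 5).
#' @return object of class \code{internal_noise_estimate}: sigma_int, pc,
#'   pa, fit_criterion, fit_mu, achieved_pa, converged.
#' @export
estimate_internal_noise <- function(pc, pa, p_yes = NULL, sigma_max = 5) {
  if (!(pc > 0 && pc < 1)) sp_input_error("pc must be in (0, 1)")
  if (!(pa > 0 && pa <= 1)) sp_input_error("pa must be in (0, 1]")
  mk <- function(sig, conv, note = "") {
    s <- sqrt(1 + sig^2)
    mc <- solve_mu_c(pc, p_yes, s)
    structure(list(sigma_int = sig, pc = pc, pa = pa,
                   fit_criterion = if (is.null(mc)) NA_real_ else mc$c,
                   fit_mu = if (is.null(mc)) NA_real_ else mc$mu,
                   achieved_pa = if (is.null(mc)) NA_real_
                                 else model_pa(mc$mu, mc$c, sig),
                   converged = conv, note = note),
              class = "internal_noise_estimate")
  }
  if (pa >= 1) return(mk(0, TRUE, "perfect agreement implies zero internal noise"))
  objective <- function(sig) {
    s <- sqrt(1 + sig^2)
    mc <- solve_mu_c(pc, p_yes, s)
    if (is.null(mc)) return(1e6)
    (model_pa(mc$mu, mc$c, sig) - pa)^2
  }
  opt <- stats::optimize(objective, c(1e-4, sigma_max), tol = 1e-5)
  ## refine around the optimum
  lo <- max(1e-4, opt$minimum - 0.2); hi <- min(sigma_max, opt$minimum + 0.2)
  opt <- stats::optimize(objective, c(lo, hi), tol = 1e-6)
  sig <- opt$minimum
  est <- mk(sig, TRUE)
  if (!is.na(est$achieved_pa) && abs(est$achieved_pa - pa) > 0.01) {
    est$converged <- FALSE
    est$note <- sprintf("no solution: nearest attainable pa = %.4f",
                        est$achieved_pa)
  }
  if (sig > sigma_max - 0.05) {
    est$converged <- FALSE
    est$note <- "sigma_int at upper search bound (estimate is a lower bound)"
  }
  est
}

#' @export
print.internal_noise_estimate <- function(x, ...) {
  cat(sprintf("<internal_noise_estimate> sigma_int=%.4f (pc=%.3f pa=%.3f c=%.3f)%s\n",
              x$sigma_int, x$pc, x$pa, x$fit_criterion,
              if (x$converged) "" else paste0(" [", x$note, "]")))
  invisible(x)
}

#' Forward double-pass simulation
#'
#' Monte-Carlo companion of [estimate_internal_noise()]: simulates
#' \code{n_pairs} two-pass trials of the same late-noise SDT model and
#' returns the observed percent correct, percent agreement, and yes-rate.
#'
#' @param n_pairs number of trial pairs.
#' @param mu signal separation (external decision-variable units).
#' @param sigma_int internal noise SD (external-SD units).
#' @param criterion decision criterion.
#' @param seed RNG seed.
#' @return list with pc, pa, p_yes and the per-pair response matrix.
#' @export
simulate_double_pass <- function(n_pairs, mu, sigma_int, criterion = 0,
                                 seed = 1L) {
  with_seed(seed, {
    q <- rep(c(1L, 0L), length.out = n_pairs)
    e <- stats::rnorm(n_pairs, mean = mu * q, sd = 1)
    r1 <- (e + stats::rnorm(n_pairs, 0, sigma_int)) > criterion
    r2 <- (e + stats::rnorm(n_pairs, 0, sigma_int)) > criterion
    correct <- (r1 == (q == 1))
    list(pc = mean(correct), pa = mean(r1 == r2),
         p_yes = mean(c(r1, r2)),
         responses = cbind(pass1 = r1, pass2 = r2, q = q))
  })
}

#' Median-split rich/poor labels
#'
#' Labels a value "rich" when it strictly exceeds the median across all
#' probe insertion points, "poor" otherwise.
#'
#' @param values numeric vector (length >= 2).
#' @return character vector of "rich"/"poor".
#' @export
median_split_labels <- function(values) {
  if (length(values) < 2) sp_input_error("need at least two values")
  ifelse(values > stats::median(values), "rich", "poor")
}

#' Summarize a probe-insertion experiment
#'
#' Per observer: d' for each of the four insertion categories (top-down x
#' bottom-up rich/poor), and rich/poor log-ratios along each map axis
#' (pooling over the other axis). Group level: medians, two-tailed Wilcoxon
#' signed-rank p-values and confidence intervals for the log-ratios.
#'
#' @param trials data.frame with columns observer_id, td_label, bu_label,
#'   q, response.
#' @param conf_level confidence level for the Wilcoxon interval (0.95).
#' @return object of class \code{experiment_summary}.
#' @export
summarize_experiment <- function(trials, conf_level = 0.95) {
  need <- c("observer_id", "td_label", "bu_label", "q", "response")
  if (!all(need %in% names(trials)))
    sp_input_error(paste("trials must have columns:", paste(need, collapse = ", ")))
  obs <- sort(unique(trials$observer_id))
  cells <- expand.grid(td = c("rich", "poor"), bu = c("rich", "poor"),
                       stringsAsFactors = FALSE)
  per_obs <- lapply(obs, function(o) {
    tr <- trials[trials$observer_id == o, ]
    d <- apply(cells, 1, function(cl) {
      sel <- tr$td_label == cl[["td"]] & tr$bu_label == cl[["bu"]]
      if (!any(sel)) return(NA_real_)
      compute_sdt(tr[sel, ])$dprime
    })
    axis_d <- function(axis, lab) {
      sel <- tr[[axis]] == lab
      if (!any(sel)) return(NA_real_)
      compute_sdt(tr[sel, ])$dprime
    }
    data.frame(observer_id = o,
               d_td_rich_bu_rich = d[cells$td == "rich" & cells$bu == "rich"],
               d_td_rich_bu_poor = d[cells$td == "rich" & cells$bu == "poor"],
               d_td_poor_bu_rich = d[cells$td == "poor" & cells$bu == "rich"],
               d_td_poor_bu_poor = d[cells$td == "poor" & cells$bu == "poor"],
               td_log_ratio = log_ratio(axis_d("td_label", "rich"),
                                        axis_d("td_label", "poor")),
               bu_log_ratio = log_ratio(axis_d("bu_label", "rich"),
                                        axis_d("bu_label", "poor")))
  })
  tab <- do.call(rbind, per_obs)
  group_stat <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2)
      return(list(median = stats::median(x), p = NA_real_,
                  ci = c(NA_real_, NA_real_), n = length(x)))
    wt <- suppressWarnings(stats::wilcox.test(x, conf.int = TRUE,
                                              conf.level = conf_level,
                                              exact = length(x) <= 25))
    list(median = stats::median(x), p = wt$p.value,
         ci = as.numeric(wt$conf.int), n = length(x))
  }
  structure(list(observers = tab,
                 td = group_stat(tab$td_log_ratio),
                 bu = group_stat(tab$bu_log_ratio),
                 conf_level = conf_level),
            class = "experiment_summary")
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat(sprintf("<experiment_summary> %d observers\n", nrow(x$observers)))
  fmt <- function(g, lab)
    cat(sprintf("  %s log-ratio: median %.4f, %d%% CI [%.4f, %.4f], Wilcoxon p = %.4g (n=%d)\n",
                lab, g$median, round(100 * x$conf_level), g$ci[1], g$ci[2],
                g$p, g$n))
  fmt(x$td, "top-down ")
  fmt(x$bu, "bottom-up")
  invisible(x)
}
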