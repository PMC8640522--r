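# Simulation-based model diagnostics: normalized prediction distribution
# errors and the prediction-corrected visual predictive check.

# Simulate `n_sim` replicate observation vectors for one subject under the
# model (new random effects and residual errors each replicate). Residual
# errors are left untruncated so that the simulated distribution matches
# the Gaussian error model the ranks are compared against.
simulate_replicates <- function(obs, pop, n_sim) {
  m <- length(obs$time)
  sims <- matrix(0, n_sim, m)
  for (r in seq_len(n_sim)) {
    eta <- draw_eta(pop)
    ind <- apply_covariates(pop, obs$cov, eta = eta)
    f <- concentration(ind, obs$reg, obs$time,
                       steady_state = obs$steady_state)
    sims[r, ] <- f + stats::rnorm(m, sd = residual_sd(f, pop))
  }
  sims
}

#' Normalized prediction distribution errors
#'
#' For each subject, simulates `n_sim` replicate observation vectors under
#' the population model, decorrelates observed and simulated vectors by the
#' inverse Cholesky factor of the empirical simulation covariance, computes
#' the prediction distribution error of each observation as its rank among
#' the simulations (clamped to `[1/(2 n_sim), 1 - 1/(2 n_sim)]`), and maps
#' it through the standard-normal quantile function. Under a correct model
#' the result is standard normal.
#'
#' @param dataset A PK dataset (see [read_pk_dataset()]); BLQ and missing
#'   rows are excluded.
#' @param pop An [mpa_params()] object.
#' @param n_sim Number of simulation replicates (at least 100).
#' @param seed Integer seed.
#' @param ridge Relative ridge added to a numerically singular simulation
#'   covariance (with a warning).
#' @return A list of class `npde_result`: `npde` (per observation, with
#'   `id` and `time`), `mean`, `variance` and `normality_p`
#'   (Shapiro-Wilk).
#' @export
npde <- function(dataset, pop, n_sim = 1000, seed = 1, ridge = 1e-8) {
  if (n_sim < 100) stop("`n_sim` must be at least 100", call. = FALSE)
  obs_list <- dataset_to_observations(dataset)
  out <- with_seed(seed, {
    res <- list()
    for (obs in obs_list) {
      keep <- obs$blq == 0
      if (!any(keep)) next
      o <- obs
      o$time <- o$time[keep]; o$conc <- o$conc[keep]; o$blq <- o$blq[keep]
      sims <- simulate_replicates(o, pop, n_sim)
      mu <- colMeans(sims)
      S <- stats::cov(sims)
      L <- tryCatch(chol(S), error = function(e) {
        warning("singular simulation covariance for subject ", o$id,
                ": ridging", call. = FALSE)
        chol(S + diag(ridge * mean(diag(S)), nrow(S)))
      })
      dec_obs <- backsolve(L, o$conc - mu, transpose = TRUE)
      dec_sim <- t(backsolve(L, t(sims) - mu, transpose = TRUE))
      pde <- (colSums(dec_sim < rep(dec_obs, each = n_sim)) ) / n_sim
      pde <- pmin(pmax(pde, 1 / (2 * n_sim)), 1 - 1 / (2 * n_sim))
      res[[length(res) + 1]] <- data.frame(id = o$id, time = o$time,
                                           npde = stats::qnorm(pde))
    }
    do.call(rbind, res)
  })
  n <- nrow(out)
  normality_p <- if (n >= 3 && n <= 5000) {
    stats::shapiro.test(out$npde)$p.value
  } else {
    NA_real_
  }
  structure(list(npde = out, mean = mean(out$npde),
                 variance = stats::var(out$npde),
                 normality_p = normality_p, n_sim = n_sim),
            class = "npde_result")
}

#' @export
print.npde_result <- function(x, ...) {
  cat(sprintf("NPDE over %d observations (%d simulations)\n",
              nrow(x$npde), x$n_sim))
  cat(sprintf("  mean %.4f, variance %.4f, normality p = %.3g\n",
              x$mean, x$variance, x$normality_p))
  invisible(x)
}

#' Prediction-corrected visual predictive check
#'
#' Observations and model simulations are prediction-corrected within time
#' bins by the ratio of the bin-median population prediction to each
#' record's own population prediction; per bin, the 5th/50th/95th
#' percentiles of the corrected simulations form the predictive band, which
#' is compared with the corrected observed percentiles.
#'
#' @param dataset A PK dataset.
#' @param pop An [mpa_params()] object.
#' @param n_sim Number of simulated replicate datasets.
#' @param bins Bin edges covering the observation times; default places
#'   edges midway between the intensive-schedule times.
#' @param seed Integer seed.
#' @return A list of class `pcvpc_result` with the per-bin band table and
#'   the fraction of corrected observations inside the 5-95% band.
#' @export
pcvpc <- function(dataset, pop, n_sim = 500, bins = NULL, seed = 1) {
  obs_list <- dataset_to_observations(dataset)
  rows <- do.call(rbind, lapply(obs_list, function(o) {
    keep <- o$blq == 0
    if (!any(keep)) return(NULL)
    ind <- apply_covariates(pop, o$cov)
    data.frame(id = o$id, time = o$time[keep], dv = o$conc[keep],
               pred = concentration(ind, o$reg, o$time[keep],
                                    steady_state = o$steady_state))
  }))
  if (is.null(bins)) {
    sched <- sampling_schedule("intensive")
    mid <- (utils::head(sched, -1) + utils::tail(sched, -1)) / 2
    bins <- c(-Inf, mid, Inf)
  }
  rows$bin <- cut(rows$time, bins, include.lowest = TRUE)
  empty <- setdiff(levels(rows$bin), unique(as.character(rows$bin)))
  if (length(empty)) {
    warning("dropping empty bin(s): ", paste(empty, collapse = ", "),
            call. = FALSE)
  }
  rows$bin <- droplevels(rows$bin)
  med_pred <- tapply(rows$pred, rows$bin, stats::median)
  rows$pc_dv <- rows$dv * as.numeric(med_pred[rows$bin]) / rows$pred
  sims <- with_seed(seed, {
    lapply(seq_len(n_sim), function(r) {
      unlist(lapply(obs_list, function(o) {
        keep <- o$blq == 0
        if (!any(keep)) return(NULL)
        eta <- draw_eta(pop)
        ind <- apply_covariates(pop, o$cov, eta = eta)
        f <- concentration(ind, o$reg, o$time[keep],
                           steady_state = o$steady_state)
        f + stats::rnorm(sum(keep), sd = residual_sd(f, pop))
      }), use.names = FALSE)
    })
  })
  sim_mat <- do.call(cbind, sims)               # rows align with `rows`
  pc_sim <- sim_mat * (as.numeric(med_pred[rows$bin]) / rows$pred)
  qs <- c(0.05, 0.5, 0.95)
  band <- do.call(rbind, lapply(levels(rows$bin), function(b) {
    in_bin <- rows$bin == b
    sim_q <- stats::quantile(pc_sim[in_bin, , drop = FALSE], qs)
    obs_q <- stats::quantile(rows$pc_dv[in_bin], qs)
    data.frame(bin = b, t_mid = stats::median(rows$time[in_bin]),
               n = sum(in_bin),
               sim_p5 = sim_q[1], sim_p50 = sim_q[2], sim_p95 = sim_q[3],
               obs_p5 = obs_q[1], obs_p50 = obs_q[2], obs_p95 = obs_q[3],
               row.names = NULL)
  }))
  lo <- band$sim_p5[match(rows$bin, band$bin)]
  hi <- band$sim_p95[match(rows$bin, band$bin)]
  inside <- mean(rows$pc_dv >= lo & rows$pc_dv <= hi)
  structure(list(band = band, inside_fraction = inside, n_sim = n_sim),
            class = "pcvpc_result")
}

#' @export
print.pcvpc_result <- function(x, ...) {
  cat(sprintf("pcVPC (%d simulations): %.1f%% of corrected observations inside the 5-95%% band\n",
              x$n_sim, 100 * x$inside_fraction))
  print(x$band, digits = 3)
  invisible(x)
}
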