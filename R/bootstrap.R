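#' Empirical quantile bounds
#'
#' Linear interpolation between order statistics (the default sample
#' quantile definition, type 7), at probabilities (1 - level)/2 and
#' 1 - (1 - level)/2.
#'
#' @param samples non-empty numeric vector.
#' @param level coverage level strictly between 0 and 1.
#' @return numeric `c(lo, hi)`.
#' @export
percentile_bounds <- function(samples, level = 0.95) {
  if (length(samples) == 0) stop_data("no samples to take quantiles of")
  if (!is.numeric(level) || length(level) != 1 || is.na(level) ||
      level <= 0 || level >= 1)
    stop_config("level must lie strictly between 0 and 1")
  alpha <- (1 - level) / 2
  unname(stats::quantile(samples, c(alpha, 1 - alpha), type = 7, names = FALSE))
}

#' Bootstrap confidence intervals for life expectancy
#'
#' Resamples animals with replacement, rebuilds the life table for each
#' replicate, and keeps only replicates that meet the eligibility rule; the
#' bounds at each age are empirical quantiles of the accepted replicate life
#' expectancies. Because a life table depends on the lifespans only through
#' their multiset, resampling is carried out as a multinomial draw over the
#' distinct lifespan values, which is distributionally identical to
#' resampling individuals and much faster.
#'
#' Replicate tables can end at an earlier final interval than the point
#' estimate's; ages present in fewer than half of the accepted replicates
#' get no bounds (reported in `support`). Rejected replicates are not
#' replaced unless `topup = TRUE`.
#'
#' @param lifespans numeric vector of lifespans (or a cohort data frame with
#'   a `lifespan_years` column).
#' @param rule an [eligibility_rule()].
#' @param iterations number of bootstrap iterations.
#' @param level confidence level.
#' @param seed integer seed; fixed seed gives bit-reproducible bounds.
#' @param method `"percentile"` (default) or `"basic"` (pivotal interval
#'   reflected about the point estimate).
#' @param topup redraw to replace ineligible iterations (capped at 10x the
#'   requested iterations).
#' @param stratum stratum label for the point-estimate table.
#' @return object of class `lt_bootstrap`: the point-estimate `table` with
#'   `e_lo`/`e_hi` filled in, per-age `replicates`, `support`,
#'   `iterations_attempted`, `iterations_accepted`, `seed`.
#' @export
bootstrap_life_table <- function(lifespans, rule = eligibility_rule(),
                                 iterations = 10000L, level = 0.95,
                                 seed = NULL,
                                 method = c("percentile", "basic"),
                                 topup = FALSE,
                                 stratum = c(scheme = "overall", label = "overall")) {
  method <- match.arg(method)
  if (is.data.frame(lifespans)) lifespans <- lifespans$lifespan_years
  point <- build_life_table(lifespans, rule, stratum)
  if (!point$eligible)
    stop_data(paste("cohort is not eligible as a whole:",
                    paste(point$reasons, collapse = "; ")))
  if (!is.null(seed)) set.seed(seed)
  n <- length(lifespans)
  tab <- table(lifespans)
  v <- as.numeric(names(tab))
  cnt <- as.vector(tab)
  xv <- as.integer(floor(v))
  frac <- v - xv
  maxage <- max(xv)
  ages <- 0:maxage
  point_ages <- point$rows$x
  min_last <- rule$min_last_interval
  min_per <- rule$min_per_interval

  keep_e <- list()    # accepted replicate e_x columns (ages x accepted)
  keep_n <- list()    # final-interval start of each accepted replicate
  attempted <- 0L
  accepted <- 0L
  budget <- if (topup) 10L * iterations else iterations
  batch <- 1000L
  revidx <- rev(seq_along(ages))
  revcs <- function(m) {
    if (nrow(m) == 1L) return(m)
    apply(m[revidx, , drop = FALSE], 2, cumsum)[revidx, , drop = FALSE]
  }
  while (if (topup) (accepted < iterations && attempted < budget)
         else attempted < iterations) {
    b <- min(batch, if (topup) budget - attempted else iterations - attempted)
    draws <- stats::rmultinom(b, n, prob = cnt / n)
    # per-interval sufficient statistics for every replicate at once
    rs_d <- rowsum(draws, xv)
    rs_f <- rowsum(draws * frac, xv)
    dmat <- fmat <- matrix(0, nrow = length(ages), ncol = b)
    at <- as.integer(rownames(rs_d)) + 1L
    dmat[at, ] <- rs_d
    fmat[at, ] <- rs_f
    lmat <- revcs(dmat)
    # mean residual lifespan at each age x: e_x = (A_x + M_x - x l_x) / l_x
    emat <- (revcs(fmat) + revcs(ages * dmat) - ages * lmat) / lmat
    # eligibility per replicate: n_j = largest age whose tail count meets the
    # last-interval minimum; all closed intervals below it must meet the
    # per-interval minimum
    okmat <- lmat >= min_last
    n_j <- rep(NA_integer_, b)
    for (j in seq_len(b)) {
      w <- which(okmat[, j])
      if (length(w) == 0) next
      nn <- ages[max(w)]
      if (nn > 0 && any(dmat[seq_len(nn), j] < min_per)) next
      n_j[j] <- nn
    }
    attempted <- attempted + b
    acc <- which(!is.na(n_j))
    if (topup && accepted + length(acc) > iterations)
      acc <- acc[seq_len(iterations - accepted)]
    if (length(acc) > 0) {
      keep_e[[length(keep_e) + 1L]] <- emat[, acc, drop = FALSE]
      keep_n[[length(keep_n) + 1L]] <- n_j[acc]
      accepted <- accepted + length(acc)
    }
  }
  if (accepted == 0L)
    stop_estimation(sprintf(
      "no bootstrap iteration met the eligibility rule (%d/%d rejected)",
      attempted, attempted))
  emat_acc <- do.call(cbind, keep_e)
  n_acc <- unlist(keep_n)
  e_reps <- lapply(point_ages, function(x) emat_acc[x + 1L, n_acc >= x])
  names(e_reps) <- point_ages
  support <- lengths(e_reps) / accepted
  e_lo <- e_hi <- rep(NA_real_, length(point_ages))
  for (i in seq_along(point_ages)) {
    if (support[i] < 0.5) next
    bounds <- percentile_bounds(e_reps[[i]], level)
    if (method == "basic") {
      pt <- point$rows$e_hat[i]
      bounds <- c(2 * pt - bounds[2], 2 * pt - bounds[1])
    }
    e_lo[i] <- bounds[1]
    e_hi[i] <- bounds[2]
  }
  low_support <- point_ages[support < 0.5]
  if (length(low_support) > 0)
    message(sprintf("no bounds at age(s) %s: present in < 50%% of accepted replicates",
                    paste(low_support, collapse = ", ")))
  outside <- which(!is.na(e_lo) &
                   (point$rows$e_hat < e_lo | point$rows$e_hat > e_hi))
  if (length(outside) > 0)
    message(sprintf("point estimate outside the interval at age(s) %s",
                    paste(point_ages[outside], collapse = ", ")))
  point$rows$e_lo <- e_lo
  point$rows$e_hi <- e_hi
  structure(list(table = point, replicates = e_reps, support = support,
                 iterations_attempted = attempted,
                 iterations_accepted = accepted,
                 level = level, method = method, seed = seed),
            class = "lt_bootstrap")
}

#' @export
print.lt_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap life table: %d/%d iterations accepted, %g%% %s intervals\n",
              x$iterations_accepted, x$iterations_attempted,
              100 * x$level, x$method))
  print(x$table)
  invisible(x)
}
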