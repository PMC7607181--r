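# Survival statistics implemented from formulas: cohort filter,
# Kaplan-Meier with Greenwood intervals, K-group logrank, Cox proportional
# hazards (Newton-Raphson, Breslow or Efron ties), median split.

#' Exclude perioperative deaths
#'
#' Removes records whose death occurred within the exclusion window after
#' surgery (default: the first month). Censored records inside the window
#' are retained: the rule applies to deaths only.
#'
#' @param records data.frame with numeric `time` (months) and logical
#'   `event` columns.
#' @param exclusion_window_months window length (default 1).
#' @return filtered data.frame; attribute `n_removed` carries the count.
#' @export
filter_survival <- function(records, exclusion_window_months = 1) {
  if (!all(c("time", "event") %in% names(records)))
    abort("records need `time` and `event` columns", "ihcmet_format_error")
  drop <- records$event & records$time <= exclusion_window_months
  out <- records[!drop, , drop = FALSE]
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' S(t) = prod over event times t_i <= t of (1 - d_i / n_i), with
#' Greenwood variance on the log scale for the 95% confidence interval:
#' Var(log S) = sum d_i / (n_i (n_i - d_i)),
#' CI = S * exp(+/- 1.96 sqrt(Var)). S(0) = 1 by definition.
#'
#' @param time numeric follow-up times (> 0).
#' @param event logical event indicator (TRUE = death).
#' @param conf_level confidence level (default 0.95).
#' @return data.frame with one row per distinct event time: `time`,
#'   `n_risk`, `n_event`, `surv`, `se_logsurv`, `lower`, `upper`. With no
#'   events the curve is flat at 1 (zero rows).
#' @export
km_estimate <- function(time, event, conf_level = 0.95) {
  if (length(time) != length(event) || any(time <= 0, na.rm = TRUE))
    abort("`time` must be > 0 and match `event`", "ihcmet_param_error")
  o <- order(time)
  time <- time[o]; event <- as.logical(event)[o]
  n <- length(time)
  etimes <- unique(time[event])
  if (!length(etimes))
    return(data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), surv = numeric(0),
                      se_logsurv = numeric(0), lower = numeric(0),
                      upper = numeric(0)))
  z <- qnorm(1 - (1 - conf_level) / 2)
  n_risk <- vapply(etimes, function(t) sum(time >= t), 0L)
  n_event <- vapply(etimes, function(t) sum(time == t & event), 0L)
  surv <- cumprod(1 - n_event / n_risk)
  gw <- cumsum(ifelse(n_risk > n_event,
                      n_event / (n_risk * (n_risk - n_event)), NA_real_))
  se <- sqrt(gw)
  lower <- ifelse(surv > 0, pmax(0, surv * exp(-z * se)), NA_real_)
  upper <- ifelse(surv > 0, pmin(1, surv * exp(z * se)), NA_real_)
  data.frame(time = etimes, n_risk = n_risk, n_event = n_event,
             surv = surv, se_logsurv = se, lower = lower, upper = upper)
}

#' K-group logrank test
#'
#' At each distinct event time the observed events per group are compared
#' with their hypergeometric expectation given the risk sets; the
#' chi-square statistic is (O - E)' V^- (O - E) over the first K - 1
#' groups, df = K - 1. Groups with no at-risk subjects at any time are
#' dropped with a warning.
#'
#' @param time numeric follow-up times.
#' @param event logical event indicator.
#' @param group group labels (>= 2 levels after dropping empty groups).
#' @return list: `statistic` (chi-square), `df`, `p.value`,
#'   `observed`, `expected` per group, `n` per group.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  keep_lvl <- levels(group)[tabulate(group) > 0L]
  if (length(keep_lvl) < length(levels(group))) {
    warning("dropping empty group(s)")
    group <- factor(group, levels = keep_lvl)
  }
  K <- nlevels(group)
  if (K < 2) abort("need >= 2 non-empty groups", "ihcmet_param_error")
  if (!any(event)) abort("need >= 1 event", "ihcmet_param_error")
  etimes <- sort(unique(time[event]))
  O <- E <- rep(0, K)
  V <- matrix(0, K, K)
  gi <- as.integer(group)
  for (t in etimes) {
    at <- time >= t
    nj <- sum(at)
    dj <- sum(time == t & event)
    nkj <- tabulate(gi[at], nbins = K)
    dkj <- tabulate(gi[time == t & event], nbins = K)
    O <- O + dkj
    E <- E + dj * nkj / nj
    if (nj > 1) {
      c1 <- dj * (nj - dj) / (nj - 1)
      V <- V + c1 * (diag(nkj / nj, K) - tcrossprod(nkj / nj))
    }
  }
  i <- seq_len(K - 1)
  d <- (O - E)[i]
  Vi <- V[i, i, drop = FALSE]
  qrV <- qr(Vi)
  if (qrV$rank < K - 1) {
    # generalized inverse via eigen decomposition
    ev <- eigen(Vi, symmetric = TRUE)
    pos <- ev$values > max(ev$values) * 1e-12
    inv <- ev$vectors[, pos, drop = FALSE] %*%
      (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
    stat <- drop(t(d) %*% inv %*% d)
    df <- sum(pos)
  } else {
    stat <- drop(t(d) %*% solve(Vi, d))
    df <- K - 1
  }
  list(statistic = stat, df = df, p.value = pchisq(stat, df,
                                                   lower.tail = FALSE),
       observed = setNames(O, levels(group)),
       expected = setNames(E, levels(group)),
       n = setNames(tabulate(gi, K), levels(group)))
}

#' Cox proportional hazards regression
#'
#' Partial-likelihood maximization by Newton-Raphson with Breslow
#' (default) or Efron handling of tied event times. Convergence when the
#' largest score component is below `tol` (default 1e-8) or after
#' `max_iter` (default 50) iterations. Returns the log hazard ratio, Wald
#' standard error, hazard ratio with 95% CI, and two-sided p per
#' covariate. Monotone-likelihood separation or non-convergence is flagged
#' and no estimates are emitted.
#'
#' @param time numeric follow-up times.
#' @param event logical event indicator.
#' @param X numeric covariate matrix (encode factors with
#'   [stats::model.matrix()]; document reference levels yourself).
#' @param ties "breslow" or "efron".
#' @param max_iter,tol Newton-Raphson controls.
#' @return list: `coefficients` data.frame (`coef`, `hr`, `se`, `z`,
#'   `p.value`, `hr_lower`, `hr_upper`), `loglik`, `iterations`,
#'   `converged`.
#' @export
cox_ph <- function(time, event, X, ties = c("breslow", "efron"),
                   max_iter = 50L, tol = 1e-8) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- length(time)
  if (nrow(X) != n || length(event) != n)
    abort("dimension mismatch", "ihcmet_param_error")
  if (!any(event)) abort("need >= 1 event", "ihcmet_param_error")
  p <- ncol(X)
  # center covariates for numerical stability (does not change coef)
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  o <- order(time)
  Xc <- Xc[o, , drop = FALSE]; tt <- time[o]; ev <- as.logical(event)[o]
  etimes <- unique(tt[ev])
  beta <- rep(0, p)
  conv <- FALSE; ll <- NA_real_; iter <- 0L; info <- NULL
  for (iter in seq_len(max_iter)) {
    eta <- drop(Xc %*% beta)
    eta <- pmin(eta, 500)           # guard overflow under separation
    w <- exp(eta)
    U <- rep(0, p); I <- matrix(0, p, p); ll <- 0
    for (t in etimes) {
      at <- tt >= t
      dset <- which(tt == t & ev)
      d <- length(dset)
      S0 <- sum(w[at])
      S1 <- colSums(Xc[at, , drop = FALSE] * w[at])
      Xat <- Xc[at, , drop = FALSE]
      S2 <- crossprod(Xat, Xat * w[at])
      xd <- colSums(Xc[dset, , drop = FALSE])
      if (ties == "breslow" || d == 1L) {
        ll <- ll + sum(eta[dset]) - d * log(S0)
        U <- U + xd - d * S1 / S0
        I <- I + d * (S2 / S0 - tcrossprod(S1 / S0))
      } else {
        S0d <- sum(w[dset])
        S1d <- colSums(Xc[dset, , drop = FALSE] * w[dset])
        Xd <- Xc[dset, , drop = FALSE]
        S2d <- crossprod(Xd, Xd * w[dset])
        ll <- ll + sum(eta[dset])
        for (l in seq_len(d) - 1L) {
          f <- l / d
          s0 <- S0 - f * S0d
          s1 <- S1 - f * S1d
          s2 <- S2 - f * S2d
          ll <- ll - log(s0)
          U <- U + xd / d - s1 / s0
          I <- I + s2 / s0 - tcrossprod(s1 / s0)
        }
      }
    }
    info <- I
    if (max(abs(U)) < tol) { conv <- TRUE; break }
    step <- tryCatch(solve(I, U), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) { conv <- FALSE; break }
    beta <- beta + step
    if (any(abs(beta) > 20)) { conv <- FALSE; break }  # separation guard
  }
  if (!conv) {
    return(list(coefficients = NULL, loglik = ll, iterations = iter,
                converged = FALSE))
  }
  se <- sqrt(diag(solve(info)))
  z <- beta / se
  cf <- data.frame(coef = beta, hr = exp(beta), se = se, z = z,
                   p.value = 2 * pnorm(-abs(z)),
                   hr_lower = exp(beta - 1.96 * se),
                   hr_upper = exp(beta + 1.96 * se),
                   row.names = colnames(X))
  list(coefficients = cf, loglik = ll, iterations = iter, converged = TRUE)
}

#' Median split into high/low expression groups
#'
#' `high` iff value strictly above the sample median; ties at the median
#' go to `low` (stated convention). All-equal input cannot form two groups
#' and raises an error.
#'
#' @param values numeric vector, n >= 2.
#' @return factor with levels `low`, `high`.
#' @export
median_split <- function(values) {
  if (length(values) < 2)
    abort("need n >= 2", "ihcmet_param_error")
  if (length(unique(values)) == 1L)
    abort("all values equal: cannot median-split into two groups",
          "ihcmet_param_error")
  med <- median(values)
  factor(ifelse(values > med, "high", "low"), levels = c("low", "high"))
}
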