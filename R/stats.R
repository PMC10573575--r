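## Longitudinal statistics: change scores and linear models with
## cluster-robust (sandwich) variance for fellow-eye clustering.

#' Per-eye change scores between two visits
#'
#' @param records Measurement records: a data frame with columns
#'   `patient_id`, `eye_id`, `mnv_type`, `visit`, `region`, `metric`,
#'   `value`, optionally `eligible`.
#' @param from_visit,to_visit Visit labels.
#' @param metric,region Optional filters; required when `records` carries
#'   more than one metric/region.
#' @param require_eligible Drop rows flagged `eligible = FALSE` (applied to
#'   CVI records; default `TRUE`).
#' @return Data frame with one row per eye present at both visits:
#'   `patient_id`, `eye_id`, `mnv_type`, `region`, `metric`, `value_from`,
#'   `value_to`, `change` (`value_to - value_from`).  Eyes missing a visit
#'   are dropped with a message; their ids are in `attr(, "dropped")`.
#' @export
change_scores <- function(records, from_visit, to_visit,
                          metric = NULL, region = NULL,
                          require_eligible = TRUE) {
  r <- records
  if (!is.null(metric)) r <- r[r$metric == metric, ]
  if (!is.null(region)) r <- r[r$region == region, ]
  if (length(unique(r$metric)) > 1L || length(unique(r$region)) > 1L)
    stop("records contain multiple metrics/regions; filter with metric=, region=")
  if (require_eligible && "eligible" %in% names(r))
    r <- r[is.na(r$eligible) | r$eligible, ]
  a <- r[r$visit == from_visit, ]
  b <- r[r$visit == to_visit, ]
  m <- merge(a[, c("patient_id", "eye_id", "mnv_type", "region", "metric", "value")],
             b[, c("eye_id", "value")],
             by = "eye_id", suffixes = c("_from", "_to"))
  dropped <- setdiff(union(a$eye_id, b$eye_id), m$eye_id)
  if (length(dropped))
    message(sprintf("change_scores: dropped %d eye(s) missing a visit: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  m$change <- m$value_to - m$value_from
  out <- m[order(m$eye_id),
           c("patient_id", "eye_id", "mnv_type", "region", "metric",
             "value_from", "value_to", "change")]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Linear regression with cluster-robust (sandwich) variance
#'
#' Ordinary least squares with the CR0/CR1 cluster-robust covariance
#' \deqn{V = c \, (X'X)^{-1} \Big[\sum_g X_g' e_g e_g' X_g\Big] (X'X)^{-1}}
#' where `g` runs over clusters (patients; fellow eyes share a cluster),
#' `c = 1` for CR0 and `c = G/(G-1) * (N-1)/(N-k)` for CR1 (the default
#' small-sample correction).  Tests use `t = beta / SE` on `G - 1` degrees
#' of freedom, two-sided.
#'
#' @param y Response vector.
#' @param X Design matrix (default: intercept only).
#' @param cluster Cluster id vector, same length as `y`.
#' @param correction `"CR1"` (default) or `"CR0"`.
#' @return An object of class `crfit`: coefficient table (`estimate`, `se`,
#'   `t`, `p`), `vcov`, `G`, `N`, `df`.
#' @export
cluster_robust_fit <- function(y, X = NULL, cluster,
                               correction = c("CR1", "CR0")) {
  correction <- match.arg(correction)
  y <- as.numeric(y)
  N <- length(y)
  if (is.null(X)) X <- matrix(1, N, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) != N || length(cluster) != N)
    stop("y, X and cluster must have matching lengths")
  k <- ncol(X)
  if (N <= k) stop("need more observations than coefficients")
  qx <- qr(X)
  if (qx$rank < k) stop("singular design matrix")
  cluster <- as.character(cluster)
  G <- length(unique(cluster))
  if (G < 2L)
    stop("cluster-robust variance needs at least 2 clusters")
  beta <- qr.coef(qx, y)
  e <- y - X %*% beta
  bread <- chol2inv(chol(crossprod(X)))
  meat <- matrix(0, k, k)
  for (g in unique(cluster)) {
    idx <- which(cluster == g)
    xe <- crossprod(X[idx, , drop = FALSE], e[idx])
    meat <- meat + tcrossprod(xe)
  }
  cfac <- if (correction == "CR1") G / (G - 1) * (N - 1) / (N - k) else 1
  V <- cfac * bread %*% meat %*% bread
  se <- sqrt(pmax(diag(V), 0))
  tval <- as.numeric(beta) / se
  df <- G - 1L
  pval <- 2 * stats::pt(-abs(tval), df = df)
  coefs <- data.frame(estimate = as.numeric(beta), se = se, t = tval,
                      p = pval, row.names = colnames(X))
  structure(list(coefficients = coefs, vcov = V, residuals = as.numeric(e),
                 G = G, N = N, df = df, correction = correction),
            class = "crfit")
}

#' @export
print.crfit <- function(x, ...) {
  cat(sprintf("Cluster-robust linear fit (%s), N = %d, G = %d clusters, df = %d\n",
              x$correction, x$N, x$G, x$df))
  print(format(x$coefficients, digits = 4))
  invisible(x)
}

#' Paired mean-change test
#'
#' Intercept-only cluster-robust fit on per-eye change scores: tests whether
#' the mean change differs from zero while accounting for fellow-eye
#' clustering.
#'
#' @param changes Numeric vector of per-eye changes.
#' @param cluster Patient ids.
#' @param correction `"CR1"` or `"CR0"`.
#' @return A `crfit`.
#' @export
paired_change_test <- function(changes, cluster, correction = "CR1") {
  cluster_robust_fit(changes, cluster = cluster, correction = correction)
}

#' MNV type-difference test on change scores
#'
#' Regression of changes on an intercept plus an indicator of type 3 MNV
#' (types 1 and 2, both arising from the choroidal circulation, are grouped);
#' the indicator coefficient is the type-3 minus type-1-or-2 difference.
#'
#' @param changes Numeric vector of per-eye changes.
#' @param mnv_type Integer vector of types (1, 2, 3).
#' @param cluster Patient ids.
#' @param correction `"CR1"` or `"CR0"`.
#' @return A `crfit`; coefficient `type3` is the group difference.
#' @export
type_difference_test <- function(changes, mnv_type, cluster,
                                 correction = "CR1") {
  ind <- as.numeric(mnv_type == 3)
  if (length(unique(ind)) < 2L)
    stop("both MNV groups (type 1 or 2 vs type 3) must be present")
  X <- cbind("(Intercept)" = 1, type3 = ind)
  cluster_robust_fit(changes, X, cluster = cluster, correction = correction)
}

## Visit-pair comparisons and the sign convention used for reporting:
## "increase" rows report to - from, "decrease" rows report from - to
## (a positive number when the measurement fell).
COMPARISONS <- list(
  pre_to_exudation = list(from = "pretreatment", to = "exudation",
                          direction = "increase"),
  exudation_to_post = list(from = "exudation", to = "post_treatment",
                           direction = "decrease"),
  pre_to_post = list(from = "pretreatment", to = "post_treatment",
                     direction = "change"))

#' Summary tables for the longitudinal analysis
#'
#' For each visit-pair comparison and each (metric, region) cell, computes
#' the visit means +/- SD over eyes with complete pairs, the mean +/- SD of
#' the per-eye change (signed per the comparison's direction), and the
#' cluster-robust p-value of the paired mean-change test; plus a by-type
#' variant comparing eyes with type 1 or 2 MNV against type 3 via the
#' group-indicator coefficient.
#'
#' @param records Measurement records (see [change_scores()]).
#' @param comparisons Subset of `c("pre_to_exudation", "exudation_to_post",
#'   "pre_to_post")`.
#' @param correction Sandwich correction, `"CR1"` (default) or `"CR0"`.
#' @param alpha Two-sided significance level (default 0.05), recorded in the
#'   output attributes.
#' @return Named list per comparison, each with data frames `all_eyes` and
#'   `by_type`.
#' @export
summarize_tables <- function(records, comparisons = names(COMPARISONS),
                             correction = "CR1", alpha = 0.05) {
  comparisons <- match.arg(comparisons, names(COMPARISONS), several.ok = TRUE)
  metrics <- unique(records$metric)
  regions <- unique(records$region)
  out <- list()
  for (cmp_name in comparisons) {
    cmp <- COMPARISONS[[cmp_name]]
    sign <- if (cmp$direction == "decrease") -1 else 1
    all_rows <- list(); type_rows <- list()
    for (met in metrics) for (reg in regions) {
      ch <- suppressMessages(
        change_scores(records, cmp$from, cmp$to, metric = met, region = reg))
      if (nrow(ch) < 2L) {
        all_rows[[length(all_rows) + 1L]] <- data.frame(
          metric = met, region = reg, direction = cmp$direction,
          n = nrow(ch), mean_from = NA, sd_from = NA, mean_to = NA,
          sd_to = NA, change_mean = NA, change_sd = NA, p_value = NA,
          note = "insufficient eyes", stringsAsFactors = FALSE)
        next
      }
      fit <- paired_change_test(ch$change, ch$patient_id,
                                correction = correction)
      all_rows[[length(all_rows) + 1L]] <- data.frame(
        metric = met, region = reg, direction = cmp$direction,
        n = nrow(ch),
        mean_from = mean(ch$value_from), sd_from = stats::sd(ch$value_from),
        mean_to = mean(ch$value_to), sd_to = stats::sd(ch$value_to),
        change_mean = sign * mean(ch$change),
        change_sd = stats::sd(ch$change),
        p_value = fit$coefficients["(Intercept)", "p"],
        note = "", stringsAsFactors = FALSE)
      for (grp in c("type_1_or_2", "type_3")) {
        sel <- if (grp == "type_3") ch$mnv_type == 3 else ch$mnv_type %in% c(1, 2)
        gch <- ch[sel, ]
        type_rows[[length(type_rows) + 1L]] <- data.frame(
          metric = met, region = reg, direction = cmp$direction, group = grp,
          n = nrow(gch),
          change_mean = if (nrow(gch)) sign * mean(gch$change) else NA,
          change_sd = if (nrow(gch) >= 2L) stats::sd(gch$change) else NA,
          note = if (nrow(gch) < 2L) "insufficient eyes" else "",
          stringsAsFactors = FALSE)
      }
      grp_p <- tryCatch({
        f <- type_difference_test(ch$change, ch$mnv_type, ch$patient_id,
                                  correction = correction)
        f$coefficients["type3", "p"]
      }, error = function(e) NA_real_)
      for (j in (length(type_rows) - 1L):length(type_rows))
        type_rows[[j]]$p_value <- grp_p
    }
    out[[cmp_name]] <- list(
      all_eyes = do.call(rbind, all_rows),
      by_type = if (length(type_rows)) do.call(rbind, type_rows) else NULL)
  }
  attr(out, "alpha") <- alpha
  attr(out, "correction") <- correction
  out
}

#' Render a summary table list as aligned text
#' @param tables Output of [summarize_tables()].
#' @return Character vector of lines (invisibly printed with `cat`).
#' @export
format_tables <- function(tables) {
  lines <- character(0)
  for (nm in names(tables)) {
    lines <- c(lines, sprintf("== %s ==", nm))
    tab <- tables[[nm]]$all_eyes
    for (i in seq_len(nrow(tab))) {
      r <- tab[i, ]
      lines <- c(lines, sprintf(
        "%-14s %-9s n=%-3d %s: %7.3f +/- %6.3f   (visit means %.3f -> %.3f)   P=%s",
        r$metric, r$region, r$n, r$direction, r$change_mean, r$change_sd,
        r$mean_from, r$mean_to,
        ifelse(is.na(r$p_value), "NA", format.pval(r$p_value, digits = 2))))
    }
  }
  lines
}
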