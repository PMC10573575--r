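## Shared, lazily built fixtures.  Heavy phantom objects are generated once
## per test run and reused across files (including the acceptance tests).

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]]))
    assign(name, build(), envir = .fixture_env)
  .fixture_env[[name]]
}

## Speckled phantom at the study conditions (desk-scale grid, 12-mm field)
test_phantom <- function() {
  fixture("phantom_noisy", function()
    generate_phantom(phantom_params(seed = 42)))
}

## Noise-free phantom for segmentation-accuracy checks
test_phantom_clean <- function() {
  fixture("phantom_clean", function()
    generate_phantom(phantom_params(seed = 11, speckle = FALSE)))
}

## Segmentation of the speckled phantom (raw + corrected + surfaces)
test_segmentation <- function() {
  fixture("segmentation", function() {
    ph <- test_phantom()
    corrected <- compensate_attenuation(ph$volume)
    ss <- segment_choroid(ph$volume, corrected = corrected)
    list(phantom = ph, corrected = corrected, surfaces = ss)
  })
}

## Three-visit longitudinal series with the programmed study-course deltas
test_series <- function() {
  fixture("series", function()
    generate_longitudinal_phantoms(phantom_params(seed = 7)))
}

## Full pipeline run on the longitudinal series
test_quantified <- function() {
  fixture("quantified", function() {
    vols <- lapply(test_series(), `[[`, "volume")
    run_quantify(vols, pipeline_config())
  })
}

## Brute-force minimum-cost path by exhaustive enumeration (small grids)
brute_force_min_path <- function(cost, max_step) {
  nx <- nrow(cost); nz <- ncol(cost)
  best <- Inf
  recurse <- function(x, z, acc) {
    acc <- acc + cost[x, z]
    if (x == nx) {
      if (acc < best) best <<- acc
      return(invisible())
    }
    for (nzt in max(1L, z - max_step):min(nz, z + max_step))
      recurse(x + 1L, nzt, acc)
  }
  for (z0 in seq_len(nz)) recurse(1L, z0, 0)
  best
}

## Brute-force Otsu threshold: exhaustive scan over the 256 bin edges with
## class statistics computed directly from the raw values
brute_force_otsu <- function(v, n_bins = 256L) {
  rng <- range(v)
  width <- (rng[2] - rng[1]) / n_bins
  best_k <- NA_integer_; best_bcv <- -Inf
  for (k in seq_len(n_bins - 1L)) {
    t <- rng[1] + k * width
    lo <- v[v < t]; hi <- v[v >= t]
    if (!length(lo) || !length(hi)) next
    bcv <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (bcv > best_bcv) {   # strict: keeps the lowest threshold on ties
      best_bcv <- bcv; best_k <- k
    }
  }
  rng[1] + best_k * width
}

## Brute-force CR0/CR1 sandwich covariance assembled per cluster
brute_force_sandwich <- function(y, X, cluster, correction = "CR1") {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  e <- as.numeric(y - X %*% beta)
  bread <- solve(t(X) %*% X)
  k <- ncol(X)
  meat <- matrix(0, k, k)
  for (g in unique(cluster)) {
    Xg <- X[cluster == g, , drop = FALSE]
    eg <- e[cluster == g]
    s <- t(Xg) %*% eg
    meat <- meat + s %*% t(s)
  }
  G <- length(unique(cluster)); N <- length(y)
  cfac <- if (correction == "CR1") G / (G - 1) * (N - 1) / (N - k) else 1
  cfac * bread %*% meat %*% bread
}

## Records whose visit means equal prescribed values exactly, with per-eye
## and per-visit variation that sums to zero (so the change-score pathway is
## exercised on non-degenerate data)
records_with_visit_means <- function(mean_from, mean_to, n, metric, region,
                                     from_visit, to_visit, seed,
                                     spread = 1) {
  set.seed(seed)
  eye_dev <- stats::rnorm(n, 0, spread); eye_dev <- eye_dev - mean(eye_dev)
  vis_dev <- stats::rnorm(n, 0, spread); vis_dev <- vis_dev - mean(vis_dev)
  ids <- sprintf("E%02d", seq_len(n))
  pats <- sprintf("P%02d", seq_len(n))
  mnv <- rep(c(1, 2, 3), length.out = n)
  rbind(
    data.frame(patient_id = pats, eye_id = ids, mnv_type = mnv,
               visit = from_visit, region = region, metric = metric,
               value = mean_from + eye_dev, eligible = TRUE,
               stringsAsFactors = FALSE),
    data.frame(patient_id = pats, eye_id = ids, mnv_type = mnv,
               visit = to_visit, region = region, metric = metric,
               value = mean_to + eye_dev + vis_dev, eligible = TRUE,
               stringsAsFactors = FALSE))
}
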