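#' Pairwise Pearson correlations between channel conductances
#'
#' @param pop a `neuron_population` (n >= 3)
#' @return symmetric correlation matrix; zero-variance channels yield `NA`
#'   rows/columns (flagged, never imputed)
#' @export
pairwise_correlations <- function(pop) {
  stopifnot(nrow(pop) >= 3)
  x <- unclass(pop)
  sds <- apply(x, 2, stats::sd)
  r <- suppressWarnings(stats::cor(x))
  r[sds == 0, ] <- NA
  r[, sds == 0] <- NA
  diag(r)[sds > 0] <- 1
  r
}

#' Correlation graph of a population
#'
#' Builds the channel-correlation graph: nodes are conductances, edges carry
#' the pairwise Pearson correlation, its sign and absolute value; edges whose
#' `|r|` falls below the threshold (default: the inverse of the number of
#' conductances, 1/8 for the STG model and 1/6 for the DA model) are dropped,
#' as are undefined correlations.
#'
#' @param pop a `neuron_population`
#' @param threshold minimum `|r|` for an edge; default `1 / ncol(pop)`
#' @return an `igraph` graph with edge attributes `r`, `sign`, `weight = |r|`
#' @export
correlation_graph <- function(pop, threshold = NULL) {
  threshold <- threshold %||% (1 / ncol(pop))
  r <- pairwise_correlations(pop)
  chans <- colnames(r)
  edges <- NULL
  for (i in seq_len(ncol(r) - 1))
    for (j in seq(i + 1, ncol(r))) {
      rij <- r[i, j]
      if (!is.na(rij) && abs(rij) >= threshold)
        edges <- rbind(edges,
                       data.frame(from = chans[i], to = chans[j], r = rij,
                                  sign = ifelse(rij > 0, "positive",
                                                "negative"),
                                  weight = abs(rij)))
    }
  gr <- igraph::graph_from_data_frame(
    edges %||% data.frame(from = character(), to = character()),
    directed = FALSE,
    vertices = data.frame(name = chans))
  gr <- igraph::set_graph_attr(gr, "threshold", threshold)
  gr
}

#' Principal component analysis of a population in conductance space
#'
#' Covariance PCA (no variable scaling, since all coordinates share mS/cm2
#' units) of the population's conductance matrix. Loading signs are fixed so
#' that each component's largest-magnitude entry is positive.
#'
#' @param pop a `neuron_population` with more members than conductances
#' @param center center the data before decomposition (default); uncentered
#'   PCA is available for through-origin analyses
#' @return list of class `cond_pca`: `variance_fraction` (non-increasing,
#'   sums to 1), `loadings` (orthonormal columns, channel order), `sdev`,
#'   `center`
#' @export
pca_population <- function(pop, center = TRUE) {
  x <- unclass(pop)
  if (nrow(x) <= ncol(x))
    stop("PCA needs more members (", nrow(x), ") than conductances (",
         ncol(x), ")")
  pr <- stats::prcomp(x, center = center, scale. = FALSE)
  load <- pr$rotation
  for (k in seq_len(ncol(load))) {
    i <- which.max(abs(load[, k]))
    if (load[i, k] < 0) load[, k] <- -load[, k]
  }
  structure(list(variance_fraction = pr$sdev^2 / sum(pr$sdev^2),
                 loadings = load, sdev = pr$sdev,
                 center = if (isTRUE(center)) pr$center
                          else setNames(rep(0, ncol(x)), colnames(x))),
            class = "cond_pca")
}

#' @export
print.cond_pca <- function(x, ...) {
  cat("Conductance-space PCA\n  variance fractions:",
      paste(sprintf("%.3f", x$variance_fraction), collapse = " "), "\n")
  invisible(x)
}

#' Homogeneous-scaling direction of a population
#'
#' The unit vector from the origin of conductance space to the population's
#' center of mass, i.e. the total-least-squares regression direction without
#' intercept. Populations generated by scaling all conductances of a template
#' lie along this ray.
#'
#' @param pop a `neuron_population`
#' @return unit vector (class `direction_vector`) in channel order
#' @export
homogeneous_scaling_direction <- function(pop) {
  cm <- colMeans(unclass(pop))
  nrm <- sqrt(sum(cm^2))
  if (nrm == 0) stop("population center of mass is at the origin")
  structure(cm / nrm, class = "direction_vector",
            description = "homogeneous-scaling")
}

#' Alignment between two directions in conductance space
#'
#' Absolute dot product of two unit vectors — the cosine of the angle between
#' the directions, invariant to the arbitrary sign of PCA loadings. 1 means
#' parallel, 0 orthogonal.
#'
#' @param u,v numeric vectors of equal length (normalized internally)
#' @return scalar in `[0, 1]`
#' @export
alignment <- function(u, v) {
  if (length(u) != length(v))
    stop("alignment: dimension mismatch (", length(u), " vs ", length(v), ")")
  u <- u / sqrt(sum(u^2))
  v <- v / sqrt(sum(v^2))
  abs(sum(u * v))
}

#' Normalize a population by input resistance
#'
#' Multiplies each member's conductance vector by its own input resistance
#' (equivalently divides by the input conductance at `V_ref`), yielding a
#' dimensionless population from which the effect of homogeneous scaling is
#' removed. Members whose input conductance is non-positive at `V_ref` are
#' excluded with a message.
#'
#' @param pop a `neuron_population`
#' @param V_ref reference voltage (mV) for the input conductance; default
#'   from [model_config()]
#' @param model the population's `cb_model`; default: rebuilt from the
#'   population's model name
#' @return a `neuron_population` of Rin-normalized members; provenance
#'   records `V_ref` and any excluded members
#' @export
normalize_by_rin <- function(pop, V_ref = NULL, model = NULL) {
  model <- model %||% build_model(attr(pop, "model"))
  V_ref <- V_ref %||% model_config(model)$analysis$V_ref
  gin <- vapply(seq_len(nrow(pop)), function(i) {
    tryCatch(input_conductance(model, member(pop, i), V_ref)$gin,
             error = function(e) NA_real_)
  }, numeric(1))
  bad <- which(!is.finite(gin) | gin <= 0)
  if (length(bad))
    message("normalize_by_rin: excluding ", length(bad),
            " unstable member(s): ", paste(bad, collapse = ", "))
  keep <- setdiff(seq_len(nrow(pop)), bad)
  pv <- attr(pop, "provenance")
  pv$normalized_by <- list(V_ref = V_ref, excluded = bad)
  new_population(model, unclass(pop)[keep, , drop = FALSE] / gin[keep], pv)
}

#' Total-least-squares regression direction of a channel pair
#'
#' Direction minimizing orthogonal distances of the pair's scatter:
#' the dominant right-singular vector of the (optionally centered) data.
#' With `through_origin = TRUE` the data are not centered, giving the
#' regression direction without intercept.
#'
#' @param pop a `neuron_population`
#' @param pair character vector of two channel names
#' @param through_origin fit without intercept (uncentered SVD)
#' @return unit 2-vector (class `direction_vector`), first component >= 0
#' @export
tls_regression <- function(pop, pair, through_origin = FALSE) {
  stopifnot(length(pair) == 2L, all(pair %in% colnames(pop)))
  x <- unclass(pop)[, pair, drop = FALSE]
  if (!through_origin) x <- scale(x, center = TRUE, scale = FALSE)
  if (all(abs(x) < 1e-300)) stop("degenerate scatter: all points equal")
  v <- svd(x)$v[, 1]
  if (v[1] < 0 || (v[1] == 0 && v[2] < 0)) v <- -v
  structure(setNames(v, pair), class = "direction_vector",
            description = if (through_origin) "TLS-through-origin"
                          else "TLS")
}
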