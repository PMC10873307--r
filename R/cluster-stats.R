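#' Pixelwise Welch's t-test between two sets of maps
#'
#' Unequal-variance two-sample t with Welch-Satterthwaite degrees of
#' freedom and two-tailed p, computed independently at every pixel. Maps
#' may be 1-D (subjects x time, for ERPs) or 2-D (subjects x freq x time,
#' for ERSPs); the first dimension always indexes subjects.
#'
#' @param a,b Numeric arrays with matching trailing dimensions and at least
#'   two subjects each.
#' @return A list with `t`, `p`, `df` (arrays of the map shape). Pixels
#'   where both groups have zero variance get t = 0 and p = 1.
#' @export
welch_t_map <- function(a, b) {
  da <- dim(a) %||% c(length(a), 1)
  db <- dim(b) %||% c(length(b), 1)
  if (!identical(da[-1], db[-1])) {
    abort("Maps must share their pixel dimensions.",
          class = "remstim_invalid_parameter")
  }
  na <- da[1]
  nb <- db[1]
  if (na < 2 || nb < 2) {
    abort("At least two subjects per condition are required.",
          class = "remstim_invalid_parameter")
  }
  am <- matrix(a, nrow = na)
  bm <- matrix(b, nrow = nb)
  ma <- colMeans(am)
  mb <- colMeans(bm)
  va <- colSums(sweep(am, 2, ma)^2) / (na - 1)
  vb <- colSums(sweep(bm, 2, mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  degen <- se2 == 0
  tt[degen] <- 0
  df[degen] <- na + nb - 2
  p <- 2 * pt(-abs(tt), df)
  p[degen] <- 1
  shape <- if (length(da) > 2) da[-1] else NULL
  reshape <- function(v) if (is.null(shape)) as.numeric(v) else array(v, shape)
  list(t = reshape(tt), p = reshape(p), df = reshape(df))
}

#' Find suprathreshold clusters
#'
#' Connected components of the sub-alpha region of a p-map, split by the
#' sign of the accompanying t-map (positive and negative clusters are kept
#' separate). Adjacency is 4-connectivity in two dimensions and
#' 2-neighbour in one dimension.
#'
#' @param p_map,t_map Congruent numeric vectors (1-D) or matrices (2-D).
#' @param alpha Pixel-level threshold.
#' @return A tibble, one row per cluster: `id`, `sign`, `size_px`, and a
#'   list-column `mask` of logical maps.
#' @export
suprathreshold_clusters <- function(p_map, t_map, alpha = 0.05) {
  pm <- if (is.matrix(p_map)) p_map else matrix(p_map, nrow = 1)
  tm <- if (is.matrix(t_map)) t_map else matrix(t_map, nrow = 1)
  stopifnot(identical(dim(pm), dim(tm)))
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- pm < alpha & sign(tm) == sgn
    if (!any(mask)) next
    lab <- label_components_cpp(mask)
    for (id in seq_len(max(lab))) {
      cm <- lab == id
      out[[length(out) + 1]] <- tibble(
        sign = if (sgn > 0) "positive" else "negative",
        size_px = sum(cm), mask = list(cm))
    }
  }
  if (length(out) == 0) {
    return(tibble(id = integer(0), sign = character(0), size_px = integer(0),
                  mask = list()))
  }
  res <- dplyr::bind_rows(out) |>
    dplyr::arrange(dplyr::desc(.data$size_px)) |>
    dplyr::mutate(id = dplyr::row_number(), .before = 1)
  res
}

# max suprathreshold cluster size (pixels, either sign) of a Welch t map
max_cluster_size <- function(a, b, alpha) {
  wt <- welch_t_map(a, b)
  pm <- if (is.matrix(wt$p)) wt$p else matrix(wt$p, nrow = 1)
  tm <- if (is.matrix(wt$t)) wt$t else matrix(wt$t, nrow = 1)
  mx <- 0L
  for (sgn in c(1, -1)) {
    mask <- pm < alpha & sign(tm) == sgn
    if (any(mask)) {
      lab <- label_components_cpp(mask)
      mx <- max(mx, max(tabulate(lab[lab > 0])))
    }
  }
  mx
}

#' Suprathreshold-cluster permutation test for paired condition maps
#'
#' Nonparametric test of condition differences in ERP (1-D) or ERSP (2-D)
#' maps: observed clusters are formed from pixels where a two-tailed
#' Welch's t between conditions has p below `alpha`, and each cluster's
#' pixel count is referred to the permutation distribution of the maximal
#' suprathreshold cluster size obtained by re-labelling the two conditions
#' within subjects. Permutations are sampled without repetition; when
#' 2^n_subjects does not exceed `n_perm` the test enumerates all sign
#' patterns exhaustively (with a message). Cluster p-values use the +1
#' smoothing (1 + #\{null >= observed\}) / (1 + n_perm).
#'
#' @param a,b Paired subject-level maps (subjects x ... arrays), same order
#'   of subjects in both.
#' @param n_perm Number of permutations (default 1600).
#' @param alpha Pixel-level threshold for cluster formation.
#' @param seed Integer seed for the permutation draw.
#' @return A list of class `cluster_test`: `clusters` (tibble from
#'   [suprathreshold_clusters()] plus `p_value`), `null_max_sizes`,
#'   `n_perm_used`, `exhaustive`, `t`, `p` (the observed maps).
#' @export
permutation_cluster_test <- function(a, b, n_perm = 1600, alpha = 0.05,
                                     seed = NULL) {
  da <- dim(a) %||% c(length(a), 1)
  db <- dim(b) %||% c(length(b), 1)
  if (da[1] != db[1]) {
    abort("Paired maps need the same number of subjects.",
          class = "remstim_invalid_parameter")
  }
  n <- da[1]
  am <- matrix(a, nrow = n)
  bm <- matrix(b, nrow = n)
  shape <- if (length(da) > 2) da[-1] else NULL
  as_map <- function(m) {
    if (is.null(shape)) matrix(m, nrow = 1) else array(m, dim = c(nrow(m), shape))
  }
  wt <- welch_t_map(as_map2(am, shape), as_map2(bm, shape))
  obs <- suprathreshold_clusters(
    if (is.null(shape)) matrix(wt$p, 1) else wt$p,
    if (is.null(shape)) matrix(wt$t, 1) else wt$t, alpha)
  exhaustive <- n <= 30 && 2^n <= n_perm
  patterns <- with_seed(seed, {
    if (exhaustive) {
      message("2^n_subjects <= n_perm; enumerating all ", 2^n,
              " sign patterns exhaustively.")
      0:(2^n - 1)
    } else if (n <= 30) {
      sample(0:(2^n - 1), n_perm, replace = FALSE)
    } else {
      # repetition probability is negligible at this n
      replicate(n_perm, sum(2^(which(runif(n) < 0.5) - 1)))
    }
  })
  null_max <- vapply(patterns, function(code) {
    flip <- floor(code / 2^(0:(n - 1))) %% 2 == 1
    ap <- am
    bp <- bm
    ap[flip, ] <- bm[flip, , drop = FALSE]
    bp[flip, ] <- am[flip, , drop = FALSE]
    max_cluster_size(as_map2(ap, shape), as_map2(bp, shape), alpha)
  }, numeric(1))
  n_used <- length(patterns)
  clusters <- obs
  clusters$p_value <- vapply(obs$size_px, function(sz) {
    (1 + sum(null_max >= sz)) / (1 + n_used)
  }, numeric(1))
  structure(list(clusters = clusters, null_max_sizes = null_max,
                 n_perm_used = n_used, exhaustive = exhaustive,
                 t = wt$t, p = wt$p),
            class = "cluster_test")
}

# reshape a subjects x pixels matrix back to subjects x map-shape
as_map2 <- function(m, shape) {
  if (is.null(shape)) m else array(m, dim = c(nrow(m), shape))
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test: %d clusters, %d permutations%s>\n",
              nrow(x$clusters), x$n_perm_used,
              if (x$exhaustive) " (exhaustive)" else ""))
  if (nrow(x$clusters) > 0) {
    print(dplyr::select(x$clusters, "id", "sign", "size_px", "p_value"))
  }
  invisible(x)
}

#' Per-electrode cluster power
#'
#' Extracts, for every subject and electrode, a summary statistic (mean or
#' median) of the dB values inside a cluster mask. Both variants of the
#' summary are in use: the mean ("average power of each identified
#' cluster") and the median ("median cluster power"); the statistic is a
#' parameter.
#'
#' @param ersp_by_subject List (one element per subject) of
#'   [compute_ersp()] trial-averaged maps, or of channels x freqs x times
#'   arrays on a common grid.
#' @param cluster_mask Logical freq x time matrix (e.g. from
#'   [suprathreshold_clusters()]).
#' @param statistic `"mean"` or `"median"`.
#' @return A tibble: `subject`, `channel`, `power_db`.
#' @export
cluster_power_per_electrode <- function(ersp_by_subject, cluster_mask,
                                        statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  fun <- if (statistic == "mean") mean else median
  if (!any(cluster_mask)) {
    abort("Empty cluster mask.", class = "remstim_invalid_parameter")
  }
  purrr::map_dfr(seq_along(ersp_by_subject), function(s) {
    e <- ersp_by_subject[[s]]
    vals <- if (inherits(e, "remstim_ersp")) e$values else e
    chans <- if (inherits(e, "remstim_ersp")) e$channels else
      (dimnames(vals)[[1]] %||% paste0("ch", seq_len(dim(vals)[1])))
    stopifnot(identical(dim(vals)[2:3], dim(cluster_mask)))
    tibble(subject = s, channel = chans,
           power_db = vapply(seq_len(dim(vals)[1]), function(c) {
             fun(vals[c, , ][cluster_mask])
           }, numeric(1)))
  })
}
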