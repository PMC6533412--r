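# Unsupervised feature-pair screening. Every unordered pair of complete,
# non-constant feature columns is clustered with k-means (k = 2, squared
# Euclidean distance); the two clusters are mapped to the metastasis labels
# a posteriori in whichever of the two ways maximizes agreement; pairs are
# ranked by mapped accuracy, ties broken by smaller Wilks' lambda, then
# lexicographic pair name. Clustering never sees the labels.

#' Seeded k-means with restarts
#'
#' k-means with squared Euclidean distance, 25 restarts and at most 300
#' iterations per restart; the best restart (minimum within-cluster sum of
#' squares) is returned. Deterministic given `seed`.
#'
#' @param points numeric vector (1-D) or n x d matrix, d in 1..2, no missing
#'   values.
#' @param k number of clusters (default 2).
#' @param seed integer RNG seed.
#' @param nstart,iter_max restart and iteration budget.
#' @return List with `assignment` (integer cluster ids 1..k), `inertia`
#'   (total within-cluster sum of squares) and `centers`.
#' @export
kmeans_cluster <- function(points, k = 2L, seed = 1L, nstart = 25L,
                           iter_max = 300L) {
  x <- if (is.null(dim(points))) matrix(points, ncol = 1L) else
    as.matrix(points)
  if (anyNA(x)) stop("missing values in clustering input", call. = FALSE)
  if (nrow(unique(x)) < k)
    stop("fewer distinct points than clusters", call. = FALSE)
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = nstart, iter.max = iter_max)
  list(assignment = unname(km$cluster), inertia = km$tot.withinss,
       centers = km$centers)
}

# Map the 2 clusters onto the labels in whichever way maximizes accuracy;
# mapped accuracy is therefore always >= 0.5.
map_clusters <- function(assignment, labels) {
  pred_a <- assignment == 1L
  acc_a <- mean(pred_a == labels)
  predicted <- if (acc_a >= 1 - acc_a) pred_a else !pred_a
  list(predicted = predicted, accuracy = mean(predicted == labels),
       confusion = confusion_from_prediction(predicted, labels))
}

modality_feature_columns <- function(table) {
  feat <- c(first_order_names(), second_order_names())
  cols <- as.vector(t(outer(GOJRAD_MODALITIES, feat, paste, sep = "_")))
  intersect(cols, names(table))
}

#' Screen one feature pair against the labels
#'
#' @param table a `feature_table`.
#' @param feature_a,feature_b column names of the pair.
#' @param labels logical metastasis labels (defaults to the table's).
#' @param seed RNG seed for k-means.
#' @param standardize z-score each feature before clustering (default); the
#'   raw squared-Euclidean scale is available with `FALSE`.
#' @return List with the pair names, `assignment`, `accuracy`, `confusion`,
#'   diagnostic `metrics` (percent), `wilks_lambda` and `manova_p`.
#' @export
screen_pair <- function(table, feature_a, feature_b,
                        labels = table$metastatic, seed = 1L,
                        standardize = TRUE) {
  x <- cbind(table[[feature_a]], table[[feature_b]])
  if (anyNA(x)) stop("pair has missing values", call. = FALSE)
  xs <- if (standardize) scale(x) else x
  km <- kmeans_cluster(xs, k = 2L, seed = seed)
  mp <- map_clusters(km$assignment, labels)
  mv <- manova_two_group(xs, labels)
  list(feature_a = feature_a, feature_b = feature_b,
       assignment = km$assignment, accuracy = mp$accuracy,
       confusion = mp$confusion, metrics = confusion_metrics(mp$confusion),
       wilks_lambda = mv$wilks_lambda, manova_p = mv$p_value)
}

#' Exhaustively screen all feature pairs
#'
#' Considers every unordered pair of distinct modality-feature columns
#' (5 modalities x 24 features when all are present). Columns with missing
#' values or zero variance are skipped with a message. Each pair gets its
#' own seed derived from `seed` plus the pair index, so results do not
#' depend on evaluation order.
#'
#' @param table a `feature_table` with a logical `metastatic` column.
#' @param labels logical labels (defaults to `table$metastatic`).
#' @param seed integer base seed.
#' @param standardize z-score features before clustering (default `TRUE`).
#' @param verbose emit a message listing skipped columns.
#' @return A `data.frame` (class `pair_screen`) with one row per screened
#'   pair: `feature_a`, `feature_b`, `accuracy`, `sn`, `sp`, `ppv`, `npv`,
#'   `acc`, `wilks_lambda`, `manova_p`, `rank`, sorted by rank.
#' @export
screen_feature_pairs <- function(table, labels = table$metastatic, seed = 1L,
                                 standardize = TRUE, verbose = FALSE) {
  labels <- as.logical(labels)
  if (sum(labels) < 2L || sum(!labels) < 2L)
    stop("need at least 2 cases per class", call. = FALSE)
  cols <- modality_feature_columns(table)
  usable <- cols[vapply(cols, function(cn) {
    v <- table[[cn]]
    !anyNA(v) && stats::sd(v) > 0
  }, TRUE)]
  skipped <- setdiff(cols, usable)
  if (verbose && length(skipped))
    message("skipped constant/incomplete columns: ",
            paste(skipped, collapse = ", "))
  if (length(usable) < 2L)
    stop("need at least 2 complete, non-constant feature columns",
         call. = FALSE)
  z <- as.matrix(table[usable])
  if (standardize) z <- scale(z)
  pairs <- utils::combn(length(usable), 2L)
  m <- ncol(pairs)
  acc <- wl <- pv <- numeric(m)
  sn <- sp <- ppv <- npv <- numeric(m)
  for (q in seq_len(m)) {
    x <- z[, pairs[, q], drop = FALSE]
    km <- kmeans_cluster(x, k = 2L, seed = seed + q)
    mp <- map_clusters(km$assignment, labels)
    mv <- manova_two_group(x, labels)
    met <- confusion_metrics(mp$confusion)
    acc[q] <- mp$accuracy; wl[q] <- mv$wilks_lambda; pv[q] <- mv$p_value
    sn[q] <- met["sn"]; sp[q] <- met["sp"]
    ppv[q] <- met["ppv"]; npv[q] <- met["npv"]
  }
  out <- data.frame(feature_a = usable[pairs[1L, ]],
                    feature_b = usable[pairs[2L, ]],
                    accuracy = acc, sn = sn, sp = sp, ppv = ppv, npv = npv,
                    acc = 100 * acc, wilks_lambda = wl, manova_p = pv,
                    stringsAsFactors = FALSE)
  ord <- order(-out$accuracy, out$wilks_lambda, out$feature_a, out$feature_b)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("pair_screen", "data.frame")
  out
}

#' Screen a single feature (1-D k-means comparator)
#'
#' The degenerate one-feature version of the pair screen, used for the
#' clinical comparators SUV_max, ADC_mean and maximum diameter.
#'
#' @param values numeric per-case values, no missing, not constant.
#' @param labels logical metastasis labels.
#' @param seed RNG seed.
#' @return As [screen_pair()], without MANOVA unless `n > 2` per class.
#' @export
screen_single_feature <- function(values, labels, seed = 1L) {
  if (anyNA(values)) stop("missing values", call. = FALSE)
  if (stats::sd(values) == 0) stop("constant input", call. = FALSE)
  km <- kmeans_cluster(values, k = 2L, seed = seed)
  mp <- map_clusters(km$assignment, as.logical(labels))
  mv <- manova_two_group(matrix(values, ncol = 1L), labels)
  list(assignment = km$assignment, accuracy = mp$accuracy,
       confusion = mp$confusion, metrics = confusion_metrics(mp$confusion),
       wilks_lambda = mv$wilks_lambda, manova_p = mv$p_value)
}

#' Write a pair screen to CSV
#'
#' @param x a `pair_screen`.
#' @param path CSV path.
#' @export
write_pair_screen <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
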