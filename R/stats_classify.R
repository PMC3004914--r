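## Correlation, normalization, hierarchical clustering and rule-based
## type classification over merged biophysical + chemical profiles.

#' Build a property matrix from a profile table
#'
#' Selects the requested columns, applies log10 to the declared columns
#' (affinities, IC50, SD and time constants span orders of magnitude)
#' and drops drugs with missing values, with a warning naming them.
#'
#' @param profiles data.frame with `drug_code` plus property columns.
#' @param columns character vector of property columns to include.
#' @param log_columns subset of `columns` to log10-transform; all values
#'   in these columns must be strictly positive.
#' @return Numeric matrix, rows named by drug code; log-transformed
#'   columns are renamed `log_<name>`. The transform map is attached as
#'   attribute `"log_columns"`.
#' @export
build_matrix <- function(profiles, columns, log_columns = character()) {
  stopifnot(is.data.frame(profiles), "drug_code" %in% names(profiles))
  missing <- setdiff(columns, names(profiles))
  if (length(missing) > 0L)
    .stopf("profiles lack column(s): %s", paste(missing, collapse = ", "))
  bad_log <- setdiff(log_columns, columns)
  if (length(bad_log) > 0L)
    .stopf("log_columns not in columns: %s", paste(bad_log, collapse = ", "))
  m <- as.matrix(profiles[, columns, drop = FALSE])
  rownames(m) <- profiles$drug_code
  for (cl in log_columns) {
    neg <- which(!is.na(m[, cl]) & m[, cl] <= 0)
    if (length(neg) > 0L)
      .stopf("non-positive value in log column '%s' for drug %s",
             cl, rownames(m)[neg[1]])
    m[, cl] <- log10(m[, cl])
  }
  colnames(m)[match(log_columns, columns)] <- paste0("log_", log_columns)
  incomplete <- rownames(m)[!stats::complete.cases(m)]
  if (length(incomplete) > 0L) {
    .warnf("dropping drug(s) with missing values: %s", paste(incomplete, collapse = ", "))
    m <- m[stats::complete.cases(m), , drop = FALSE]
  }
  attr(m, "log_columns") <- log_columns
  m
}

#' Column-wise z-scoring
#'
#' Subtracts each column's mean over all drugs and divides by its sample
#' standard deviation (n - 1), so every property enters clustering with
#' equal weight.
#'
#' @param matrix numeric matrix (>= 2 rows).
#' @return Matrix of the same shape with column means 0 and SDs 1.
#' @export
zscore <- function(matrix) {
  stopifnot(is.matrix(matrix))
  if (nrow(matrix) < 2L) .stopf("z-scoring needs at least 2 rows")
  s <- apply(matrix, 2L, stats::sd)
  if (any(s == 0))
    .stopf("constant column(s) cannot be z-scored: %s",
           paste(colnames(matrix)[s == 0], collapse = ", "))
  scale(matrix, center = TRUE, scale = s)[, , drop = FALSE]
}

#' Pearson cross-correlation matrix with significance flags
#'
#' Pairwise-complete Pearson correlations with two-sided t-test
#' p-values, flagged at two alpha levels (`*`, `**`). No
#' multiple-testing correction is applied; the flags describe per-pair
#' evidence only. Cells with fewer than `min_pairs` complete pairs are
#' set to NA.
#'
#' @param matrix numeric matrix, columns = properties.
#' @param alpha_levels two decreasing significance levels.
#' @param min_pairs minimum complete pairs per cell (default 4).
#' @return Object of class `sci_cormat`: list with matrices `r`, `p`,
#'   `n` and character `flags` (`""`, `"*"`, `"**"`).
#' @export
correlation_matrix <- function(matrix, alpha_levels = c(0.05, 0.01), min_pairs = 4L) {
  stopifnot(is.matrix(matrix), length(alpha_levels) == 2L,
            alpha_levels[1] > alpha_levels[2])
  p <- ncol(matrix)
  r <- pmat <- nmat <- matrix(NA_real_, p, p,
                              dimnames = list(colnames(matrix), colnames(matrix)))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      ok <- stats::complete.cases(matrix[, c(i, j), drop = FALSE])
      nmat[i, j] <- sum(ok)
      if (i == j) { r[i, j] <- 1; pmat[i, j] <- 0; next }
      if (sum(ok) < min_pairs) next
      ct <- stats::cor.test(matrix[ok, i], matrix[ok, j], method = "pearson")
      r[i, j] <- unname(ct$estimate)
      pmat[i, j] <- ct$p.value
    }
  }
  flags <- matrix("", p, p, dimnames = dimnames(r))
  flags[!is.na(pmat) & pmat < alpha_levels[1]] <- "*"
  flags[!is.na(pmat) & pmat < alpha_levels[2]] <- "**"
  diag(flags) <- ""
  structure(list(r = r, p = pmat, n = nmat, flags = flags,
                 alpha_levels = alpha_levels), class = "sci_cormat")
}

#' @export
print.sci_cormat <- function(x, digits = 2, ...) {
  out <- matrix(paste0(format(round(x$r, digits)), x$flags),
                nrow(x$r), ncol(x$r), dimnames = dimnames(x$r))
  out[is.na(x$r)] <- "."
  print(out, quote = FALSE)
  cat(sprintf("flags: * p<%g, ** p<%g (uncorrected)\n",
              x$alpha_levels[1], x$alpha_levels[2]))
  invisible(x)
}

#' Agglomerative hierarchical clustering (WPGMA or Ward)
#'
#' Euclidean distances over the (typically z-scored) property matrix,
#' agglomerated with the weighted pair-group average rule (WPGMA:
#' the new cluster's distance to any third cluster is the unweighted
#' mean of the two merged clusters' distances) or Ward's
#' variance-minimizing rule.
#'
#' @param matrix numeric matrix, rows = drugs.
#' @param method `"wpgma"` or `"ward"`.
#' @param metric distance metric (only `"euclidean"` supported).
#' @return An [stats::hclust] tree with leaf labels = drug codes and
#'   attribute `"sci_method"`.
#' @export
hcluster <- function(matrix, method = c("wpgma", "ward"), metric = "euclidean") {
  method <- match.arg(method)
  if (metric != "euclidean") .stopf("only the euclidean metric is supported")
  if (nrow(matrix) < 2L) .stopf("clustering needs at least 2 rows")
  d <- stats::dist(matrix, method = "euclidean")
  tree <- stats::hclust(d, method = switch(method, wpgma = "mcquitty", ward = "ward.D2"))
  attr(tree, "sci_method") <- method
  tree
}

#' Cut a linkage tree into flat clusters
#'
#' @param tree an [stats::hclust] tree from [hcluster()].
#' @param n_clusters number of clusters, or
#' @param height cut height (linkage distance); exactly one of the two.
#' @return Named integer vector of cluster labels (stable across runs).
#' @export
cut_tree <- function(tree, n_clusters = NULL, height = NULL) {
  stopifnot(inherits(tree, "hclust"), xor(is.null(n_clusters), is.null(height)))
  n_leaves <- length(tree$labels)
  if (!is.null(n_clusters) && n_clusters > n_leaves)
    .stopf("n_clusters (%d) exceeds number of leaves (%d)", n_clusters, n_leaves)
  stats::cutree(tree, k = n_clusters, h = height)
}

#' Export a linkage tree as a Newick string (and optionally a file)
#'
#' Merge heights become branch lengths so dendrogram geometry survives
#' the export; consumable by any tree viewer.
#'
#' @param tree an [stats::hclust] tree.
#' @param path optional output file.
#' @return The Newick string, invisibly if written to file.
#' @export
linkage_to_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Merge table of a linkage tree
#'
#' @param tree an [stats::hclust] tree.
#' @return data.frame with one row per merge: the two merged items
#'   (negative = leaf index, positive = earlier merge) and the linkage
#'   distance.
#' @export
merge_table <- function(tree) {
  data.frame(merge1 = tree$merge[, 1], merge2 = tree$merge[, 2],
             linkage_distance = tree$height)
}

#' Default rule thresholds for inhibition-type classification
#'
#' The boxes default to the observed property ranges of the named types:
#' Type 1 (high potency, slow kinetics, partial reversibility,
#' use-dependence), Type 2 (low potency, fast kinetics, nearly full
#' reversibility; split into use-dependent and non-use-dependent), and
#' Type 3 (apparent irreversibility with the offset time constant at the
#' reporting cap). A relative tolerance absorbs the rounding of
#' published thresholds.
#'
#' @param rel_tol relative tolerance applied at every box edge.
#' @return A nested list of thresholds, suitable for [classify_types()].
#' @export
default_type_rules <- function(rel_tol = 0.01) {
  list(rel_tol = rel_tol,
       type1 = list(Ki = c(0.73, 6.1), IC50 = c(14, 43), tau = c(10, 53),
                    Rev = c(0.2, 0.6), UD = c(1.09, 1.66)),
       type2 = list(Ki = c(17, 88), IC50_min = 95, tau_max = 27,
                    Rev_min = 0.75, UD_split = 1.1),
       type3 = list(Rev_max = 0.05, tau_off_min = 500))
}

#' Classify drugs into inhibition types
#'
#' Rule-based classification over the merged profile: Type 3 first
#' (irreversible, offset at cap), then the full Type 1 and Type 2 boxes;
#' drugs matching parts of both the Type 1 and Type 2 boxes are Type 4
#' (intermediate); anything else is unclassified. Type 2 is split by
#' use-dependence at `UD_split`.
#'
#' @param profiles data.frame with columns `drug_code`, `IC50_uM`, `Rev`,
#'   `UD`, `tau_on_s`, `tau_off_s`, `Ki_kapp_uM`.
#' @param rules threshold list from [default_type_rules()].
#' @return data.frame with `drug_code` and `type` in
#'   `{Type1, Type2_UD, Type2_nonUD, Type3, Type4, unclassified}`.
#' @export
classify_types <- function(profiles, rules = default_type_rules()) {
  need <- c("drug_code", "IC50_uM", "Rev", "UD", "tau_on_s", "tau_off_s", "Ki_kapp_uM")
  stopifnot(all(need %in% names(profiles)))
  tol <- rules$rel_tol
  in_range <- function(x, lo, hi) !is.na(x) & x >= lo * (1 - tol) & x <= hi * (1 + tol)
  ge <- function(x, lo) !is.na(x) & x >= lo * (1 - tol)
  le <- function(x, hi) !is.na(x) & x <= hi * (1 + tol)

  type <- character(nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    p <- profiles[i, ]
    t1 <- c(Ki = in_range(p$Ki_kapp_uM, rules$type1$Ki[1], rules$type1$Ki[2]),
            IC50 = in_range(p$IC50_uM, rules$type1$IC50[1], rules$type1$IC50[2]),
            tau = in_range(p$tau_on_s, rules$type1$tau[1], rules$type1$tau[2]) &&
                  in_range(p$tau_off_s, rules$type1$tau[1], rules$type1$tau[2]),
            Rev = in_range(p$Rev, rules$type1$Rev[1], rules$type1$Rev[2]),
            UD = in_range(p$UD, rules$type1$UD[1], rules$type1$UD[2]))
    t2 <- c(Ki = in_range(p$Ki_kapp_uM, rules$type2$Ki[1], rules$type2$Ki[2]),
            IC50 = ge(p$IC50_uM, rules$type2$IC50_min),
            tau = le(p$tau_on_s, rules$type2$tau_max) &&
                  le(p$tau_off_s, rules$type2$tau_max),
            Rev = ge(p$Rev, rules$type2$Rev_min))
    type[i] <-
      if (le(p$Rev, rules$type3$Rev_max) && ge(p$tau_off_s, rules$type3$tau_off_min))
        "Type3"
      else if (all(t1)) "Type1"
      else if (all(t2)) {
        if (p$UD >= rules$type2$UD_split) "Type2_UD" else "Type2_nonUD"
      }
      else if (any(t1) && any(t2)) "Type4"
      else "unclassified"
  }
  data.frame(drug_code = profiles$drug_code, type = type, stringsAsFactors = FALSE)
}

#' Min-max normalized radar-diagram table
#'
#' Scales every axis to `[0, 1]` over the drug set (constant columns map
#' to 0.5 by convention), producing per-drug polygons consumable by any
#' plotting tool.
#'
#' @param profiles data.frame with `drug_code` and the axis columns.
#' @param columns axis columns.
#' @param log_columns columns scaled on the log10 axis first.
#' @return data.frame: `drug_code` plus one `[0, 1]` column per axis.
#' @export
export_radar <- function(profiles, columns, log_columns = character()) {
  m <- build_matrix(profiles, columns, log_columns)
  scaled <- apply(m, 2L, function(x) {
    rng <- range(x)
    if (diff(rng) == 0) rep(0.5, length(x)) else (x - rng[1]) / diff(rng)
  })
  data.frame(drug_code = rownames(m), scaled, row.names = NULL,
             check.names = FALSE, stringsAsFactors = FALSE)
}
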