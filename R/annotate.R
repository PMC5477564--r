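#' Pearson correlation distance between cells
#'
#' `d(i, j) = 1 - cor(cell_i, cell_j)` across genes (columns of `logm`
#' are cells). Symmetric, zero diagonal, bounded by `[0, 2]`, and
#' invariant to positive affine rescaling of any cell.
#'
#' @param logm log2(RPM+1) matrix (genes x cells), typically restricted
#'   to expressed genes.
#' @return A `dist` object over cells.
#' @export
pearson_distance <- function(logm) {
  if (ncol(logm) < 2L || nrow(logm) < 2L) {
    stop_user("pearson_distance needs at least 2 cells and 2 genes")
  }
  sds <- apply(logm, 2L, stats::sd)
  if (any(sds == 0)) {
    stop_user("zero-variance cell: ",
              paste(colnames(logm)[sds == 0], collapse = ", "))
  }
  stats::as.dist(1 - stats::cor(logm))
}

#' Unsupervised hierarchical clustering, Ward linkage
#'
#' Agglomerative clustering of a distance matrix under the ward.D2
#' criterion (squared-dissimilarity Lance-Williams update), i.e.
#' `stats::hclust(d, method = "ward.D2")` — the routine conventionally
#' paired with Pearson correlation distance for expression data. Merge
#' heights are non-decreasing.
#'
#' @param d a `dist` object, e.g. from [pearson_distance()].
#' @return An `hclust` object (merge history, heights, labels).
#' @export
uhc_ward <- function(d) {
  stats::hclust(d, method = "ward.D2")
}

#' Cut a dendrogram into k groups
#'
#' Removes the `k - 1` highest merges of the dendrogram.
#'
#' @param dend an `hclust` object.
#' @param k number of clusters, `1 <= k <= n`.
#' @return integer cluster assignment named by leaf label.
#' @export
cut_clusters <- function(dend, k) {
  n <- length(dend$labels %||% dend$order)
  if (!is_count1(k) || k < 1 || k > n) {
    stop_user("k must be an integer in [1, ", n, "]")
  }
  stats::cutree(dend, k = k)
}

#' Export a dendrogram in Newick format
#' @param dend an `hclust` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(dend, path) {
  ph <- ape::as.phylo(dend)
  ape::write.tree(ph, file = path)
  invisible(path)
}

#' Seeded two-dimensional t-SNE embedding of cells
#'
#' Embeds cells (columns of `logm`) in 2-D with t-SNE at the given
#' perplexity. The embedding is deterministic for a fixed seed; only the
#' contract (2-D, perplexity-parameterised, seeded) is guaranteed, not
#' any particular layout.
#'
#' @param logm log2(RPM+1) matrix (genes x cells).
#' @param seed RNG seed.
#' @param perplexity t-SNE perplexity; requires at least
#'   `3 * perplexity + 1` cells.
#' @return numeric matrix (cells x 2) with cell ids as rownames.
#' @export
tsne_embed <- function(logm, seed = 1, perplexity = 30) {
  n <- ncol(logm)
  if (n < 3 * perplexity + 1) {
    stop_user("too few cells (", n, ") for perplexity ", perplexity,
              "; need at least ", 3 * perplexity + 1)
  }
  emb <- with_seed(seed, {
    Rtsne::Rtsne(t(logm), dims = 2L, perplexity = perplexity,
                 check_duplicates = FALSE, pca = TRUE)$Y
  })
  rownames(emb) <- colnames(logm)
  colnames(emb) <- c("tsne1", "tsne2")
  emb
}

#' Expression-state thresholds for marker logic
#'
#' On the log2(RPM+1) scale a gene is "(+)" (on) above `theta_on`, "(-)"
#' (off) below `theta_off`, and "low" in between (`(theta_off,
#' theta_on]`). The defaults (4 and 2) align the "on" state with the
#' expressed-gene cutoff.
#'
#' @param theta_on on threshold (strict lower bound for "(+)").
#' @param theta_off off threshold (strict upper bound for "(-)").
#' @return list of class `sc3_thresholds`.
#' @export
thresholds <- function(theta_on = 4, theta_off = 2) {
  if (!(theta_off < theta_on)) stop_user("theta_off must be < theta_on")
  structure(list(theta_on = theta_on, theta_off = theta_off),
            class = "sc3_thresholds")
}

#' Define a marker rule for one lineage
#'
#' A rule is a boolean requirement over named genes: every gene in `on`
#' must be "(+)", every gene in `off` "(-)", every gene in `low` "low",
#' and at least one gene in `any_on` "(+)". The four sets must be
#' pairwise disjoint.
#'
#' @param label lineage name.
#' @param on,off,low,any_on character vectors of gene names.
#' @param priority integer; lower numbers are evaluated first.
#' @return list of class `sc3_marker_rule`.
#' @export
marker_rule <- function(label, on = character(0), off = character(0),
                        low = character(0), any_on = character(0),
                        priority = 1L) {
  sets <- list(on = on, off = off, low = low, any_on = any_on)
  all_genes <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(all_genes)) {
    stop_user("marker_rule(", label, "): gene sets must be pairwise disjoint")
  }
  structure(c(list(label = label, priority = as.integer(priority)), sets),
            class = "sc3_marker_rule")
}

#' Default lineage marker rules
#'
#' The nine boolean marker combinations used to annotate early-embryo,
#' germ-cell and extraembryonic lineages, ordered so that the more
#' specific rules win first (first match by priority):
#' early PGC (PRDM1+/TFAP2C+/SOX17+/SOX2-), late PGC
#' (POU5F1+/NANOG+/TFAP2C+/SOX2-), post-implantation EPI
#' (POU5F1+/NANOG+/SOX2+/PRDM14+/T-/GATA4-), gastrulating
#' (POU5F1+/NANOG low/PRDM14 low/any of T, GATA4, GATA6 +), hypoblast
#' (SOX17+/GATA4+/GATA6+/NANOG-), trophectoderm
#' (TFAP2C+/GATA3+/GATA6+/NANOG-), pre-implantation EPI
#' (NANOG+/SOX2+/GATA6-/TFAP2C-), visceral/yolk-sac endoderm (POU5F1
#' low/FOXA1+), extraembryonic mesenchyme (POU5F1 low/COL6A1+).
#' The two PGC rules share TFAP2C+/SOX2-; only the PRDM1/SOX17
#' requirement separates the early from the late stage, which is why the
#' early-PGC rule is ranked first.
#'
#' @return list of [marker_rule()]s, sorted by priority.
#' @export
default_rules <- function() {
  list(
    marker_rule("ePGC", on = c("PRDM1", "TFAP2C", "SOX17"),
                off = "SOX2", priority = 1L),
    marker_rule("lPGC", on = c("POU5F1", "NANOG", "TFAP2C"),
                off = "SOX2", priority = 2L),
    marker_rule("Post-EPI", on = c("POU5F1", "NANOG", "SOX2", "PRDM14"),
                off = c("T", "GATA4"), priority = 3L),
    marker_rule("Gastrulating", on = "POU5F1", low = c("NANOG", "PRDM14"),
                any_on = c("T", "GATA4", "GATA6"), priority = 4L),
    marker_rule("Hypoblast", on = c("SOX17", "GATA4", "GATA6"),
                off = "NANOG", priority = 5L),
    marker_rule("TE", on = c("TFAP2C", "GATA3", "GATA6"),
                off = "NANOG", priority = 6L),
    marker_rule("Pre-EPI", on = c("NANOG", "SOX2"),
                off = c("GATA6", "TFAP2C"), priority = 7L),
    marker_rule("VE/YE", on = "FOXA1", low = "POU5F1", priority = 8L),
    marker_rule("EXMC", on = "COL6A1", low = "POU5F1", priority = 9L)
  )
}

rule_genes <- function(rule) {
  unique(c(rule$on, rule$off, rule$low, rule$any_on))
}

eval_rule <- function(rule, v, th) {
  state <- function(x) {
    ifelse(x > th$theta_on, "on", ifelse(x < th$theta_off, "off", "low"))
  }
  checks <- c(
    stats::setNames(state(v[rule$on]) == "on",
                    paste0(rule$on, "(+)", recycle0 = TRUE)),
    stats::setNames(state(v[rule$off]) == "off",
                    paste0(rule$off, "(-)", recycle0 = TRUE)),
    stats::setNames(state(v[rule$low]) == "low",
                    paste0(rule$low, "(low)", recycle0 = TRUE))
  )
  if (length(rule$any_on)) {
    checks <- c(checks, stats::setNames(
      any(state(v[rule$any_on]) == "on"),
      paste0("any(", paste(rule$any_on, collapse = ","), ")(+)")
    ))
  }
  checks
}

#' Classify cells by marker-rule logic
#'
#' Evaluates the rules in priority order against each cell's log2(RPM+1)
#' values; the first rule whose conditions all hold assigns its label.
#' Cells matching no rule are `"UNCLASSIFIED"`. Rules referencing genes
#' absent from the matrix (by rowname) are skipped for the whole cohort
#' with a warning. The result is deterministic and does not depend on
#' gene-row ordering.
#'
#' @param logm log2(RPM+1) matrix; rownames are gene names.
#' @param rules list of [marker_rule()]s (default [default_rules()]).
#' @param th an `sc3_thresholds` object.
#' @param trace if `TRUE` (default), attach per-cell rule evaluation
#'   traces as attribute `"trace"`.
#' @return data.frame with `cell_id` and `label`; attribute `"trace"`
#'   holds, per cell, each evaluated rule's named condition results.
#' @export
classify_cells <- function(logm, rules = default_rules(), th = thresholds(),
                           trace = TRUE) {
  rules <- rules[order(vapply(rules, `[[`, 1L, "priority"))]
  usable <- vapply(rules, function(r) {
    miss <- setdiff(rule_genes(r), rownames(logm))
    if (length(miss)) {
      warning("rule '", r$label, "' skipped: missing gene(s) ",
              paste(miss, collapse = ", "), call. = FALSE)
      FALSE
    } else {
      TRUE
    }
  }, logical(1L))
  rules <- rules[usable]
  cells <- colnames(logm)
  labels <- rep("UNCLASSIFIED", length(cells))
  traces <- if (trace) vector("list", length(cells)) else NULL
  for (ci in seq_along(cells)) {
    v <- logm[, ci]
    names(v) <- rownames(logm)
    cell_trace <- list()
    for (r in rules) {
      checks <- eval_rule(r, v, th)
      if (trace) cell_trace[[r$label]] <- checks
      if (all(checks)) {
        labels[ci] <- r$label
        break
      }
    }
    if (trace) traces[[ci]] <- cell_trace
  }
  out <- data.frame(cell_id = cells, label = labels,
                    stringsAsFactors = FALSE)
  if (trace) {
    names(traces) <- cells
    attr(out, "trace") <- traces
  }
  out
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same cells
#' (1 = identical up to relabeling, ~0 = random).
#'
#' @param a,b vectors of cluster labels, equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_user("labelings differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- sum_a * sum_b / n
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}
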