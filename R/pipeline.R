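RUN_CONFIG_FIELDS <- c(
  "gff", "chrom_sizes", "reads", "out_dir", "seed",
  "max_extension", "biotype_filter_order", "spike_prefix", "denominator",
  "expressed_threshold", "expressed_min_cells",
  "theta_on", "theta_off", "k_clusters", "perplexity",
  "name_mapping", "ct_table", "tally_table",
  "provenance"
)

#' Build a pipeline run configuration
#'
#' A flat key-value document describing one end-to-end run
#' (extend -> quantify -> qc -> annotate). Unknown keys are rejected.
#' The `provenance` entry is an inert metadata block (e.g. the upstream
#' trimming/alignment options a dataset was produced with); it is carried
#' into the run log but never interpreted.
#'
#' @param gff input GFF3 annotation path.
#' @param chrom_sizes chromosome-length TSV path.
#' @param reads BED6 read path.
#' @param out_dir output directory.
#' @param seed RNG seed used for every stochastic stage.
#' @param max_extension,biotype_filter_order see [extension_config()].
#' @param spike_prefix spike-in chromosome prefix.
#' @param denominator RPM denominator, see [to_rpm()].
#' @param expressed_threshold,expressed_min_cells see [expressed_genes()].
#' @param theta_on,theta_off see [thresholds()].
#' @param k_clusters number of clusters to cut (0 = skip clustering).
#' @param perplexity t-SNE perplexity (embedding is skipped when the
#'   cohort is too small for it).
#' @param name_mapping,ct_table,tally_table optional input paths.
#' @param provenance named list of inert metadata strings.
#' @return list of class `sc3_run_config`.
#' @export
run_config <- function(gff, chrom_sizes, reads, out_dir,
                       seed = 1, max_extension = 10000,
                       biotype_filter_order = "before_extension",
                       spike_prefix = "ERCC-", denominator = "assigned",
                       expressed_threshold = 4, expressed_min_cells = 1,
                       theta_on = 4, theta_off = 2, k_clusters = 0,
                       perplexity = 30, name_mapping = NULL,
                       ct_table = NULL, tally_table = NULL,
                       provenance = list()) {
  cfg <- list(gff = gff, chrom_sizes = chrom_sizes, reads = reads,
              out_dir = out_dir, seed = seed,
              max_extension = max_extension,
              biotype_filter_order = biotype_filter_order,
              spike_prefix = spike_prefix, denominator = denominator,
              expressed_threshold = expressed_threshold,
              expressed_min_cells = expressed_min_cells,
              theta_on = theta_on, theta_off = theta_off,
              k_clusters = k_clusters, perplexity = perplexity,
              name_mapping = name_mapping, ct_table = ct_table,
              tally_table = tally_table, provenance = provenance)
  structure(cfg, class = "sc3_run_config")
}

#' Write a run configuration to disk (flat JSON)
#' @param cfg an `sc3_run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a run configuration, rejecting unknown keys
#' @param path JSON path written by [write_run_config()] (or by hand).
#' @return An `sc3_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_user("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), RUN_CONFIG_FIELDS)
  if (length(unknown)) {
    stop_user("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  need <- c("gff", "chrom_sizes", "reads", "out_dir")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop_user("config missing required key(s): ", paste(miss, collapse = ", "))
  }
  do.call(run_config, raw)
}

log_msg <- function(...) message("[sc3kit] ", ...)

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_user("stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full pipeline
#'
#' Executes the four stages in order — annotation extension, read
#' quantification, quality control, clustering/annotation — writing
#' every artifact under `cfg$out_dir` and a `run_log.json` recording the
#' configuration, a hash of it, per-stage object counts, and the inert
#' provenance block. Reruns with the same configuration produce
#' identical outputs.
#'
#' @param cfg an `sc3_run_config` (see [run_config()]).
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "sc3_run_config"))
  for (f in c("gff", "chrom_sizes", "reads")) {
    if (!file.exists(cfg[[f]])) {
      stop_user("input file for '", f, "' not found: ", cfg[[f]])
    }
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(cfg$out_dir, "run_config.json")
  write_run_config(cfg, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  log <- list(config_hash = cfg_hash, provenance = cfg$provenance,
              stages = list())

  ## stage 1: extend
  res <- run_stage("extend", {
    layout <- read_chrom_sizes(cfg$chrom_sizes)
    ann <- read_gff3(cfg$gff, layout)
    if (!is.null(cfg$name_mapping)) {
      ann <- apply_name_mapping(ann, read_name_mapping(cfg$name_mapping))
    }
    ecfg <- extension_config(max_extension = cfg$max_extension,
                             biotype_filter_order = cfg$biotype_filter_order)
    ext <- extend_all(ann, ecfg)
    write_gff3(ext, file.path(cfg$out_dir, "extended.gff3"))
    list(layout = layout, ann = ann, ext = ext, ecfg = ecfg)
  })
  log$stages$extend <- list(genes_in = n_genes(res$ann),
                            genes_out = n_genes(res$ext))
  log_msg("extend: ", n_genes(res$ann), " -> ", n_genes(res$ext), " genes")

  ## stage 2: quantify
  quant <- run_stage("quantify", {
    reads <- read_bed_reads(cfg$reads)
    cm <- count_cells(reads, res$ext, spike_prefix = cfg$spike_prefix)
    rpm <- to_rpm(cm, denominator = cfg$denominator)
    logm <- log2_rpm1(rpm)
    write_matrix_tsv(cm$counts, file.path(cfg$out_dir, "counts.tsv"))
    write_matrix_tsv(rpm, file.path(cfg$out_dir, "rpm.tsv"))
    write_matrix_tsv(logm, file.path(cfg$out_dir, "log2_rpm1.tsv"))
    utils::write.table(cm$tallies, file.path(cfg$out_dir, "tallies.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(reads = reads, cm = cm, rpm = rpm, logm = logm)
  })
  log$stages$quantify <- list(reads = nrow(quant$reads),
                              cells = ncol(quant$cm$counts),
                              assigned = sum(quant$cm$tallies$assigned))
  log_msg("quantify: ", nrow(quant$reads), " reads, ",
          ncol(quant$cm$counts), " cells")

  ## stage 3: qc
  qc <- run_stage("qc", {
    out <- list()
    out$tally_pass <- if (!is.null(cfg$tally_table)) {
      tly <- read_tally(cfg$tally_table)
      all(check_tally(tly))
    } else {
      internal <- data.frame(
        sample_id = quant$cm$tallies$cell_id,
        total_reads = quant$cm$tallies$assigned + quant$cm$tallies$ambiguous +
          quant$cm$tallies$unassigned + quant$cm$tallies$spike_in,
        sc3seq_mapped = quant$cm$tallies$assigned,
        mapped_others = quant$cm$tallies$ambiguous,
        control_rna = quant$cm$tallies$spike_in,
        low_quality_adaptor_polyA = 0L,
        unmapped = quant$cm$tallies$unassigned)
      all(check_tally(internal))
    }
    out$prescreen <- if (!is.null(cfg$ct_table)) {
      prescreen_ct(read_ct(cfg$ct_table))
    } else {
      NULL
    }
    prof <- tts_metaprofile(quant$reads, res$ann, assign_ann = res$ext,
                            spike_prefix = cfg$spike_prefix)
    expr_genes <- expressed_genes(quant$logm,
                                  threshold = cfg$expressed_threshold,
                                  min_cells = cfg$expressed_min_cells)
    pct <- if (length(expr_genes)) {
      expression_percentiles(quant$logm, expr_genes)
    } else {
      NULL
    }
    utils::write.table(
      data.frame(offset = prof$offsets, mean_kilo_rpm = prof$mean),
      file.path(cfg$out_dir, "tts_metaprofile.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(pct)) {
      utils::write.table(pct, file.path(cfg$out_dir, "percentiles.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(tally_pass = out$tally_pass, prescreen = out$prescreen,
         profile = prof, expressed = expr_genes, percentiles = pct)
  })
  log$stages$qc <- list(tally_pass = qc$tally_pass,
                        expressed_genes = length(qc$expressed))
  log_msg("qc: ", length(qc$expressed), " expressed genes; tallies ",
          if (isTRUE(qc$tally_pass)) "pass" else "FAIL")

  ## stage 4: annotate
  annot <- run_stage("annotate", {
    sub <- if (length(qc$expressed) >= 2) {
      quant$logm[qc$expressed, , drop = FALSE]
    } else {
      quant$logm
    }
    th <- thresholds(cfg$theta_on, cfg$theta_off)
    rules <- default_rules()
    present <- vapply(rules, function(r) {
      all(rule_genes(r) %in% rownames(quant$logm))
    }, logical(1L))
    cls <- if (any(present)) {
      classify_cells(quant$logm, rules[present], th = th, trace = FALSE)
    } else {
      log_msg("annotate: no marker-rule genes in the matrix; ",
              "skipping rule classification")
      data.frame(cell_id = colnames(quant$logm), label = "UNCLASSIFIED",
                 stringsAsFactors = FALSE)
    }
    out <- list(classes = cls)
    usable <- ncol(sub) >= 2 &&
      all(apply(sub, 2L, stats::sd) > 0)
    if (cfg$k_clusters >= 1 && usable) {
      dend <- uhc_ward(pearson_distance(sub))
      out$clusters <- cut_clusters(dend, min(cfg$k_clusters, ncol(sub)))
      write_dendrogram_newick(dend, file.path(cfg$out_dir, "dendrogram.nwk"))
      cls$cluster <- out$clusters[cls$cell_id]
    }
    if (ncol(sub) >= 3 * cfg$perplexity + 1) {
      emb <- tsne_embed(sub, seed = cfg$seed, perplexity = cfg$perplexity)
      utils::write.table(
        data.frame(cell_id = rownames(emb), emb),
        file.path(cfg$out_dir, "tsne.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      out$embedding <- emb
    }
    utils::write.table(cls, file.path(cfg$out_dir, "labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out
  })
  log$stages$annotate <- list(
    labels = as.list(table(annot$classes$label)),
    clustered = !is.null(annot$clusters),
    embedded = !is.null(annot$embedding))
  log_msg("annotate: ",
          sum(annot$classes$label != "UNCLASSIFIED"), "/",
          nrow(annot$classes), " cells classified")

  jsonlite::write_json(log, file.path(cfg$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(list(extend = res, quant = quant, qc = qc, annotate = annot,
                 log = log))
}
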