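#' Run the full analysis pipeline
#'
#' Chains the stages end to end: optional simulation, differential
#' expression, category enrichment, per-condition co-expression networks,
#' k-core decomposition and core-regulator ranking. Every stage artifact
#' is written under `out_dir` as TSV (networks additionally as GraphML)
#' and a JSON manifest records parameters, row counts and MD5 checksums;
#' the same configuration yields byte-identical artifacts and checksums.
#'
#' @param config named list (or path to a YAML file holding one) with
#'   either a `simulate` block (arguments for [simulation_config()]) or
#'   `matrix`/`design`/`annotation` file paths, plus optional thresholds
#'   `fc_threshold` (default 2), `fdr_threshold` (0.05), `p_threshold`
#'   (NULL) and `cor_threshold` (0.999).
#' @param out_dir output directory, created if needed.
#' @return invisibly, the manifest list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  fc <- config$fc_threshold %||% 2
  fdr <- config$fdr_threshold %||% 0.05
  p_thr <- config$p_threshold
  r_thr <- config$cor_threshold %||% 0.999
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", {
      cfg <- do.call(simulation_config, config$simulate)
      out <- generate_dataset(cfg)
      ann <- generate_annotation(out$truth, cfg, rownames(out$matrix))
      out$annotation <- ann$annotation
      out$boosted <- ann$boosted
      out
    })
    mat <- sim$matrix
    design <- sim$design
    annotation <- sim$annotation
    truth <- sim$truth
    write_expression_matrix(mat, file.path(out_dir, "matrix.tsv"))
    utils::write.table(design, file.path(out_dir, "design.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(annotation, file.path(out_dir, "annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(de_genes = truth$de_genes,
           modules = truth$modules,
           boosted_categories = sim$boosted),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  } else {
    for (field in c("matrix", "design", "annotation")) {
      if (is.null(config[[field]])) {
        stop("pipeline config is missing '", field, "'", call. = FALSE)
      }
    }
    for (field in c("matrix", "design", "annotation")) {
      if (!file.exists(config[[field]])) {
        stop("pipeline input '", field, "' not found: ", config[[field]],
             call. = FALSE)
      }
    }
    mat <- stage("read", read_expression_matrix(config$matrix))
    design <- stage("read", read_design(config$design))
    annotation <- stage("read", read_annotation(config$annotation))
  }

  degs <- stage("dge", differential_expression(mat, design, fc, fdr, p_thr))
  utils::write.table(degs, file.path(out_dir, "degs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  selected <- degs$gene[degs$selected]

  enr <- stage("enrich", {
    background <- intersect(rownames(mat), unique(annotation$gene))
    enrich(intersect(selected, background), annotation, background)
  })
  utils::write.table(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  labs <- sort(unique(design$condition))
  nets <- stage("network", {
    net_genes <- if (length(selected) >= 2L) selected else rownames(mat)
    lapply(stats::setNames(labs, labs), function(lab) {
      cols <- design$sample[design$condition == lab]
      corr <- pearson_matrix(mat[net_genes, cols, drop = FALSE])
      build_network(corr, threshold = r_thr, condition = lab)
    })
  })
  kcores <- stage("kcore", lapply(nets, kcore_decompose))
  for (lab in labs) {
    write_network(nets[[lab]], file.path(out_dir, paste0("network_", lab)))
  }
  regs <- stage("regulators", core_regulators(nets[[1L]], nets[[2L]]))
  utils::write.table(regs, file.path(out_dir, "core_regulators.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  artifacts <- list.files(out_dir, pattern = "\\.(tsv|json|graphml)$")
  artifacts <- setdiff(artifacts, "manifest.json")
  checksums <- tools::md5sum(file.path(out_dir, artifacts))
  names(checksums) <- artifacts
  sim_par <- config$simulate
  if (!is.null(sim_par$modules)) {
    sim_par$modules <- lapply(sim_par$modules, unclass)
  }
  manifest <- list(
    package = "ruminet",
    version = as.character(utils::packageVersion("ruminet")),
    parameters = list(fc_threshold = fc, fdr_threshold = fdr,
                      p_threshold = p_thr, cor_threshold = r_thr,
                      simulate = sim_par),
    counts = list(
      genes = nrow(mat), samples = ncol(mat),
      deg_selected = length(selected),
      deg_up = sum(degs$selected & degs$direction == "up"),
      deg_down = sum(degs$selected & degs$direction == "down"),
      categories = nrow(enr),
      network = lapply(stats::setNames(labs, labs), function(lab) {
        list(nodes = length(nets[[lab]]$nodes),
             edges = nrow(nets[[lab]]$edges),
             max_k = kcores[[lab]]$max_k)
      })
    ),
    checksums = as.list(checksums)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a human-readable markdown summary of a pipeline run
#'
#' Summarises DEG counts, the top enriched categories with their
#' enrichment ratios, per-condition network sizes and maximum k-cores,
#' and the top core regulators. Regeneration from the same run directory
#' is idempotent.
#'
#' @param out_dir a directory written by [run_pipeline()].
#' @param n_top rows to show in the enrichment and regulator sections.
#' @return the report as a character vector of markdown lines (invisibly);
#'   also written to `report.md` in `out_dir`.
#' @export
render_report <- function(out_dir, n_top = 10L) {
  manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
  enr <- utils::read.delim(file.path(out_dir, "enrichment.tsv"),
                           stringsAsFactors = FALSE)
  regs <- utils::read.delim(file.path(out_dir, "core_regulators.tsv"),
                            stringsAsFactors = FALSE)
  cn <- manifest$counts
  lines <- c(
    "# Pipeline run summary",
    "",
    sprintf("- genes: %s, samples: %s", cn$genes, cn$samples),
    sprintf("- selected DEGs: %s (up %s / down %s)",
            cn$deg_selected, cn$deg_up, cn$deg_down),
    "",
    "## Top enriched categories",
    ""
  )
  if (nrow(enr)) {
    top <- utils::head(enr, n_top)
    lines <- c(lines,
               "| category | nf/n | p_fisher | fdr_bh | Re |",
               "|---|---|---|---|---|",
               sprintf("| %s | %d/%d | %.3g | %.3g | %.2f |",
                       top$category, top$nf, top$n, top$p_fisher,
                       top$fdr_bh, top$re))
  } else {
    lines <- c(lines, "(no categories tested)")
  }
  lines <- c(lines, "", "## Condition networks", "")
  for (lab in names(cn$network)) {
    nw <- cn$network[[lab]]
    lines <- c(lines, sprintf("- %s: %s nodes, %s edges, max k-core %s",
                              lab, nw$nodes, nw$edges, nw$max_k))
  }
  lines <- c(lines, "", "## Top core regulators (|degree difference|)", "")
  if (nrow(regs)) {
    top <- utils::head(regs, n_top)
    lines <- c(lines,
               "| gene | degree A | degree B | diff |",
               "|---|---|---|---|",
               sprintf("| %s | %d | %d | %d |", top$gene, top$degree_A,
                       top$degree_B, top$degree_diff))
  } else {
    lines <- c(lines, "(no genes in the networks)")
  }
  writeLines(lines, file.path(out_dir, "report.md"))
  invisible(lines)
}
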