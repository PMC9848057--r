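# End-to-end pipeline: expression -> composition screen -> array stats ->
# Ks/dating -> CNE decay, with a machine-readable manifest.

.default_thresholds <- list(
  fold = 5, detect = 1, z = 1, group_max = 7L, tyr_cutoff = 0.05,
  decay_cut = 0.5, intact_cut = 0.9, fold_cut = 2, alpha = 0.05,
  mu = 2e-9, min_identity = 0.6)

#' Build and validate a pipeline configuration
#'
#' Thresholds default to the study's printed values (fold 5, detection TPM 1,
#' Z 1, tyrosine cutoff 5%, decay/intact coverage cuts 50%/90%, differential
#' fold cut 2, alpha 0.05, clock rate 2e-9). The configuration serializes to
#' JSON and round-trips unchanged.
#'
#' @param expression_tsv,replicate_map_tsv TPM matrix and sample-to-tissue
#'   map (TSV with columns `sample`, `tissue`).
#' @param cds_fasta CDS FASTA; `protein_fasta` optionally cross-validates.
#' @param loci_file GFF3 or BED gene loci.
#' @param de_a,de_b Tissue labels contrasted by the differential screen
#'   (e.g. dorsal vs abdominal skin).
#' @param anchor_tissue Tissue anchoring "related" gene sets (default
#'   `"skin"`).
#' @param protein_fasta,family_file,cne_fasta,cne_hits,cne_regions Optional
#'   inputs (`family_file`: one gene id per line; `cne_hits`: outfmt6/PAF;
#'   `cne_regions`: TSV `cne_id`, `region`).
#' @param hits_format `"outfmt6"` or `"paf"`.
#' @param thresholds Named list overriding any default threshold.
#' @param seed Integer seed recorded in the manifest.
#' @param out_dir Output directory.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(expression_tsv, replicate_map_tsv, cds_fasta,
                            loci_file, de_a, de_b, anchor_tissue = "skin",
                            protein_fasta = NULL, family_file = NULL,
                            cne_fasta = NULL, cne_hits = NULL,
                            cne_regions = NULL,
                            hits_format = "outfmt6",
                            thresholds = list(), seed = 1L,
                            out_dir = "arrayscan_out") {
  th <- utils::modifyList(.default_thresholds, thresholds)
  cfg <- list(expression_tsv = expression_tsv,
              replicate_map_tsv = replicate_map_tsv,
              cds_fasta = cds_fasta, protein_fasta = protein_fasta,
              loci_file = loci_file, family_file = family_file,
              cne_fasta = cne_fasta, cne_hits = cne_hits,
              cne_regions = cne_regions, hits_format = hits_format,
              de_a = de_a, de_b = de_b, anchor_tissue = anchor_tissue,
              thresholds = th, seed = as.integer(seed), out_dir = out_dir)
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks threshold domains and the presence of every referenced input file
#' before any stage runs.
#'
#' @param cfg A `pipeline_config` (or plain list with the same fields).
#' @return `cfg`, invisibly; errors on the first violation.
#' @export
validate_config <- function(cfg) {
  th <- cfg$thresholds
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg)
  chk(th$alpha > 0 && th$alpha < 1, "alpha must be in (0, 1)")
  chk(th$fold >= 1, "fold must be >= 1")
  chk(th$fold_cut >= 1, "fold_cut must be >= 1")
  chk(th$detect >= 0, "detect must be >= 0")
  chk(th$mu > 0, "mu must be > 0")
  chk(th$tyr_cutoff >= 0 && th$tyr_cutoff <= 1, "tyr_cutoff must be in [0, 1]")
  chk(th$decay_cut > 0 && th$decay_cut <= th$intact_cut &&
        th$intact_cut <= 1, "need 0 < decay_cut <= intact_cut <= 1")
  chk(th$min_identity >= 0 && th$min_identity <= 1,
      "min_identity must be in [0, 1]")
  chk(th$group_max >= 2, "group_max must be >= 2")
  for (f in c("expression_tsv", "replicate_map_tsv", "cds_fasta",
              "loci_file", "protein_fasta", "family_file", "cne_fasta",
              "cne_hits", "cne_regions")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop("invalid config: ", f, " does not exist: ", cfg[[f]])
    }
  }
  invisible(cfg)
}

#' Read a pipeline configuration from JSON
#' @param path JSON file produced by [write_config()] (or hand-written).
#' @return A validated `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$thresholds <- as.list(raw$thresholds)
  cfg <- utils::modifyList(
    list(anchor_tissue = "skin", hits_format = "outfmt6", seed = 1L,
         out_dir = "arrayscan_out"), raw)
  th <- utils::modifyList(.default_thresholds, as.list(raw$thresholds))
  # JSON drops the integer/double distinction; restore the documented types
  th <- lapply(th, as.numeric)
  th$group_max <- as.integer(th$group_max)
  cfg$thresholds <- th[names(.default_thresholds)]
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write a pipeline configuration as JSON
#' @param cfg A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

# FNV-1a style content hash over a canonicalized config (field order and
# absent-vs-NULL optional fields do not matter; no digest dependency)
.config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  cfg <- cfg[order(names(cfg))]
  cfg$thresholds <- cfg$thresholds[order(names(cfg$thresholds))]
  bytes <- utf8ToInt(as.character(
    jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)))
  h <- 216613626
  for (b in bytes) {
    h <- (bitwXor(as.integer(h), as.integer(b)) * 16777619) %% 2^31
  }
  sprintf("%08x", h)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Stage order: expression classification and differential screen,
#' composition and tyrosine screen, tandem-array statistics, neighbor-pair
#' Ks and clock dating, CNE decay (when CNE inputs are configured). Outputs
#' are staged and moved into `out_dir` only when every stage succeeds, so a
#' failing stage never leaves partially overwritten results; the failing
#' stage is named in the error. Reruns with the same config and seed produce
#' byte-identical outputs.
#'
#' @param cfg A `pipeline_config`.
#' @return The manifest (list) invisibly; files written to `cfg$out_dir`:
#'   `classes.tsv`, `de.tsv`, `composition.tsv`, `array.json`, `ks.tsv`,
#'   `cne.tsv` (optional), `manifest.json`.
#' @export
run_full <- function(cfg) {
  validate_config(cfg)
  th <- cfg$thresholds
  set.seed(cfg$seed)
  staging <- file.path(cfg$out_dir, ".staging")
  dir.create(staging, recursive = TRUE, showWarnings = FALSE)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  artifacts <- character(0)
  emit <- function(name) artifacts <<- c(artifacts, name)

  # --- stage 1: expression classification + differential screen -----------
  .stage("expression", {
    expr <- read_expression(cfg$expression_tsv,
                            utils::read.delim(cfg$replicate_map_tsv,
                                              stringsAsFactors = FALSE))
    classes <- classify_genes(expr, fold_threshold = th$fold,
                              detect_threshold = th$detect,
                              z_threshold = th$z, group_max = th$group_max)
    utils::write.table(classes, file.path(staging, "classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("classes.tsv")
    raw <- utils::read.delim(cfg$expression_tsv, check.names = FALSE)
    vals <- as.matrix(raw[, -1L, drop = FALSE]); rownames(vals) <- raw[[1L]]
    map <- expr$replicate_map
    cols_a <- map$sample[map$tissue == cfg$de_a]
    cols_b <- map$sample[map$tissue == cfg$de_b]
    de <- differential_screen(vals[, cols_a, drop = FALSE],
                              vals[, cols_b, drop = FALSE], classes,
                              fold_cut = th$fold_cut, alpha = th$alpha,
                              anchor_tissue = cfg$anchor_tissue)
    utils::write.table(de, file.path(staging, "de.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit("de.tsv")
    classes
  }) -> classes

  # --- stage 2: residue composition + tyrosine screen ---------------------
  .stage("composition", {
    cds <- read_fasta(cfg$cds_fasta, "nucleotide")
    prot <- if (!is.null(cfg$protein_fasta)) {
      read_fasta(cfg$protein_fasta, "protein")
    } else NULL
    records <- build_coding_records(cds, prot)
    comp <- composition(records)
    screen_ids <- intersect(comp$gene_id, classes$gene_id)
    screen <- tyrosine_screen(comp[comp$gene_id %in% screen_ids, ],
                              classes, tyr_cutoff = th$tyr_cutoff,
                              anchor_tissue = cfg$anchor_tissue)
    comp$tyrosine_screen <- comp$gene_id %in% screen$genes
    utils::write.table(comp, file.path(staging, "composition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("composition.tsv")
    records
  }) -> records

  # --- stage 3: tandem array statistics -----------------------------------
  .stage("array", {
    loci <- read_loci(cfg$loci_file)
    fam <- if (!is.null(cfg$family_file)) readLines(cfg$family_file) else NULL
    genes <- intersect(records$gene_id, loci$gene_id)
    if (!is.null(fam)) genes <- intersect(genes, fam)
    # analyze the contig carrying the most family genes
    contig <- names(sort(table(loci$contig[match(genes, loci$gene_id)]),
                         decreasing = TRUE))[1L]
    on_ctg <- genes[loci$contig[match(genes, loci$gene_id)] == contig]
    report <- neighbor_identity_profile(records, loci, family_filter = on_ctg)
    jsonlite::write_json(
      list(schema = "arrayscan/array_report/1",
           contig = report$contig,
           ordered_genes = report$ordered_genes,
           neighbor_identities = as.list(report$neighbor_identities),
           mean_neighbor_identity = report$mean_neighbor_identity,
           tail_to_head = report$tail_to_head,
           clades = report$clades,
           clade_sizes = report$clade_sizes),
      file.path(staging, "array.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    emit("array.json")
    report
  }) -> report

  # --- stage 4: neighbor-pair Ks and clock dating -------------------------
  .stage("ks", {
    ids <- report$ordered_genes
    rows <- lapply(seq_len(length(ids) - 1L), function(k) {
      est <- ng86_ks(records[match(ids[k], records$gene_id), ],
                     records[match(ids[k + 1L], records$gene_id), ],
                     mu = th$mu)
      data.frame(id_a = est$id_a, id_b = est$id_b, S = est$S, N = est$N,
                 Sd = est$Sd, Nd = est$Nd, pS = est$pS, Ks = est$Ks,
                 Ka = est$Ka, T_years = est$T, saturated = est$saturated,
                 stringsAsFactors = FALSE)
    })
    ks_tab <- do.call(rbind, rows)
    utils::write.table(ks_tab, file.path(staging, "ks.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit("ks.tsv")
  })

  # --- stage 5: CNE decay (optional) --------------------------------------
  if (!is.null(cfg$cne_fasta) && !is.null(cfg$cne_hits)) {
    .stage("cne", {
      cnes <- read_fasta(cfg$cne_fasta, "nucleotide")
      hits <- read_hits(cfg$cne_hits, cfg$hits_format)
      rep_cne <- coverage_from_hits(nchar(cnes), hits,
                                    min_identity = th$min_identity,
                                    decay_cut = th$decay_cut,
                                    intact_cut = th$intact_cut)
      utils::write.table(rep_cne, file.path(staging, "cne.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      emit("cne.tsv")
    })
  }

  manifest <- list(schema = "arrayscan/manifest/1",
                   package_version = as.character(
                     utils::packageVersion("arrayscan")),
                   config = unclass(cfg),
                   config_hash = .config_hash(cfg),
                   seed = cfg$seed,
                   artifacts = artifacts)
  jsonlite::write_json(manifest, file.path(staging, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  for (f in c(artifacts, "manifest.json")) {
    file.copy(file.path(staging, f), file.path(cfg$out_dir, f),
              overwrite = TRUE)
  }
  invisible(manifest)
}
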