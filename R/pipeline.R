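#' End-to-end characterisation pipeline
#'
#' Composes the stages over one FASTA-derived proteome and its domain
#' annotations: length filter and family/subgroup classification,
#' physicochemical profiles, motif and dehydrin-segment hits, best-window
#' helix analysis, HRSA scores, composition/GRAVY scatter data, and (when
#' a DEG table is supplied) the differential-expression summary. All
#' outputs land in one bundle directory as TSV/JSON, each stage logged
#' with its record count, and the configuration echoed (with a content
#' hash) so two runs on identical inputs are byte-identical.
#'
#' @name pipeline
NULL

# tiny rolling hash over a character scalar; enough to fingerprint a
# config echo (not cryptographic)
.config_hash <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% (2^31 - 1)
  sprintf("%08x", h)
}

.write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# append the config hash as a column; safe on zero-row tables
.with_hash <- function(d, hash) {
  d$config_hash <- rep(hash, nrow(d))
  d
}

#' Run the full pipeline
#'
#' @param set a `proteome_set` (e.g. from [read_fasta()])
#' @param annotations domain annotation data frame (protein_id, pfam_id,
#'   evalue)
#' @param out_dir output bundle directory (created if needed)
#' @param deg_table optional DEG data frame; when omitted only the DEG
#'   summary is skipped
#' @param config list of thresholds overriding the defaults: evalue_max,
#'   min_length, min_identity, fdr_max, min_abs_log2fc, gly_min,
#'   gravy_max, helix_width, tmh_width, tmh_min_mean_kd
#' @param registry motif registry
#' @return invisible list of the in-memory tables (families, physchem,
#'   motifs, segments, helix, hrsa, fig1, deg_summary)
#' @export
run_pipeline <- function(set, annotations, out_dir, deg_table = NULL,
                         config = list(), registry = load_registry()) {
  stopifnot(inherits(set, "proteome_set"))
  defaults <- list(evalue_max = 1e-5, min_length = 100, min_identity = 0.8,
                   fdr_max = 0.05, min_abs_log2fc = 2, gly_min = 6,
                   gravy_max = -1.0, helix_width = 11, tmh_width = 19,
                   tmh_min_mean_kd = 1.6)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config option(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  hash <- .config_hash(as.character(cfg_json))
  log_lines <- c(paste0("leaprofiler ",
                        as.character(utils::packageVersion("leaprofiler"))),
                 paste0("config_hash=", hash),
                 paste0("input_records=", nrow(set)))
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    res
  }

  kept <- stage("length_filter",
                filter_by_length(set, cfg$min_length, quiet = TRUE))
  log_lines <- c(log_lines, paste0("after_length_filter=", nrow(kept)))

  fam <- stage("classify",
               classify_proteome(kept, annotations, registry,
                                 evalue_max = cfg$evalue_max,
                                 min_length = cfg$min_length,
                                 min_identity = cfg$min_identity))
  .write_tsv(.with_hash(fam, hash), file.path(out_dir, "families.tsv"))
  log_lines <- c(log_lines, paste0("classified=", sum(fam$family != "unclassified")))

  phys <- stage("physchem",
                physchem_table(kept, gly_min = cfg$gly_min,
                               gravy_max = cfg$gravy_max))
  .write_tsv(.with_hash(phys, hash), file.path(out_dir, "physchem.tsv"))

  mot <- stage("motifs", {
    rows <- lapply(seq_len(nrow(kept)), function(i) {
      hits <- do.call(rbind, lapply(seq_len(nrow(registry)), function(k)
        scan_motif(kept$sequence[i], registry[k, ], cfg$min_identity)))
      if (is.null(hits) || nrow(hits) == 0) return(NULL)
      cbind(id = kept$id[i], hits)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(id = character(), motif = character(),
                        start = integer(), end = integer(),
                        start_1based = integer(), end_1based = integer(),
                        identity = numeric(), matched_text = character())
    out
  })
  .write_tsv(.with_hash(mot, hash), file.path(out_dir, "motifs.tsv"))

  seg <- stage("segments", {
    rows <- lapply(seq_len(nrow(kept)), function(i) {
      s <- detect_dehydrin_segments(kept$sequence[i])
      if (nrow(s) == 0) return(NULL)
      cbind(id = kept$id[i], s)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(id = character(), kind = character(),
                        start = integer(), end = integer(),
                        start_1based = integer(), end_1based = integer(),
                        matched_text = character())
    out
  })
  .write_tsv(.with_hash(seg, hash), file.path(out_dir, "segments.tsv"))

  hel <- stage("helix", helix_table(kept, width = cfg$helix_width))
  .write_tsv(.with_hash(hel, hash), file.path(out_dir, "helix.tsv"))

  hr <- stage("hrsa", hrsa_table(kept))
  .write_tsv(.with_hash(hr, hash), file.path(out_dir, "hrsa.tsv"))

  fig1 <- stage("fig1_data", {
    panels <- gly_gravy_table(kept, gly_min = cfg$gly_min,
                              gravy_max = cfg$gravy_max)
    do.call(rbind, lapply(names(panels), function(p) {
      d <- panels[[p]]
      data.frame(panel = p, id = d$id, pct = d$pct, gravy = d$gravy,
                 hydrophilin = if ("hydrophilin" %in% names(d))
                   d$hydrophilin else NA,
                 stringsAsFactors = FALSE)
    }))
  })
  .write_tsv(.with_hash(fig1, hash), file.path(out_dir, "fig1_data.tsv"))

  deg_summary <- NULL
  if (!is.null(deg_table)) {
    deg_summary <- stage("deg", {
      flt <- filter_degs(deg_table, cfg$fdr_max, cfg$min_abs_log2fc)
      s <- summarize_degs(flt)
      s$per_group <- as.list(stats::setNames(
        lapply(seq_len(nrow(s$per_group)), function(i)
          list(up = s$per_group$up[i], down = s$per_group$down[i])),
        s$per_group$subgroup))
      s$config_hash <- hash
      s
    })
    jsonlite::write_json(deg_summary, file.path(out_dir, "deg_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_lines <- c(log_lines, paste0("deg_rows=", deg_summary$total))
  } else {
    log_lines <- c(log_lines, "deg_rows=skipped")
  }

  writeLines(c(log_lines, paste0("config=", as.character(cfg_json))),
             file.path(out_dir, "run_log.txt"))
  invisible(list(families = fam, physchem = phys, motifs = mot,
                 segments = seg, helix = hel, hrsa = hr, fig1 = fig1,
                 deg_summary = deg_summary, config = cfg,
                 config_hash = hash))
}
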