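#' Consensus motif registry
#'
#' The 28 family consensus motifs (M1.1 ... M7.2) with their family label,
#' printed length, discovery e-value, consensus string and the GRAVY value
#' printed alongside them. Degenerate patterns use bracket notation:
#' `[XY]` is a choice, `[_N]` one optional position. The built-in entries
#' are plain literal consensus strings; degenerate patterns appear in user
#' overrides and in the dehydrin K-segment grammar.
#'
#' Two printed quirks are carried verbatim and never "corrected": the M5.2
#' row prints 21 aa against a 29-character consensus (the string is taken
#' as authoritative), and the M4.1/M4.3/M4.4 printed GRAVY values do not
#' recompute from their consensus strings under any standard scale
#' (M4.3/M4.4 appear transposed). `gravy_printed` stores what is printed.
#'
#' @name motif_registry
NULL

.builtin_motifs <- function() {
  tab <- c(
    "M1.1|LEA1|50|1.25e-52|TKATVQEKAEQMKTRDPLQKEMATQKKEAKIQEAERQKQEARQQNSAAKH|-1.786",
    "M1.2|LEA1|21|3.8e-21|MQAAKETAANVAASANSGMEK|-0.352",
    "M2.1|LEA2|50|5.4e-55|IEETIGFGKPTADVTDVDLKDINLEKADYVVDVLVKNPYPIPIPLIDINY|0.048",
    "M2.2|LEA2|50|2.7e-55|KSTYADIGPGWIIPYRLKVDLIVDVPVFGRLTLPLEKKGEIPIPYKPDID|-0.018",
    "M2.3|LEA2|50|5.1e-63|IRFDKFSFEETVATLHLKLENKNDFDLGLKDLDYEVWLCNVSIGGAYMKK|-0.268",
    "M2.4|LEA2|50|1.1e-44|TLNLTVTVRNPNFYSIKYDSSTVSIGYRGNKLGRVTIPAGRIGARSSQRV|-0.328",
    "M2.5|LEA2|50|1.9e-64|ITFRPKDFGSALWDMIRGKGTGYTIKGNINVDTPFGFMKLPISKEGGTTC|-0.238",
    "M2.6|LEA2|29|1.9e-34|SGLIPDAGSLKAHGSTTVKVPICLIYDDI|0.444",
    "M2.7|LEA2|50|3.1e-57|NATLQLERVEIMSDVILLLEDLAKGEIMFDTEVDISGKLRVFFFDLPLKT|0.376",
    "M2.8|LEA2|21|1.6e-22|RNPNKRIGIYYDQIDAYASYK|-1.200",
    "M2.9|LEA2|24|1.2e-28|GGGKRINDKGWPECNVIMEEGKYD|-1.204",
    "M3.1|LEA3|41|1.8e-53|TYDKNPDEEHAFSAVVPDNVIPPQTQQYWAPHPKTGVFGPA|-0.817",
    "M3.2|LEA3|29|1.6e-36|SVSNGGADSVLEQKAFFRPLEDLDKPHHP|-0.766",
    "M3.3|LEA3|29|2.4e-35|MAANLQSRGLASFSKQFVIRVRSRDSTII|0.048",
    "M3.4|LEA3|50|1.9e-48|IRMLNKESEEPTKISWVPDPVTGYYRPENKATEIDAAELRRILIKDNTRR|-0.994",
    "M3.5|LEA3|6|1e-8|RRGVHV|-0.700",
    "M4.1|LEA4|29|8.5e-29|AKDYVADKAKEAKDSAAEKAKETKDKAGE|-1.617",
    "M4.2|LEA4|29|NA|IIGSLIGTVQGTVEHAKEAVLGKSQEASE|0.059",
    "M4.3|LEA4|36|NA|AKMKAEDTTEAAKETYEETKENARKKMEEMKIVGEG|-1.962",
    "M4.4|LEA4|21|NA|AKEKAKEAKDSAKDKAGETKD|-1.438",
    "M5.1|LEA5|50|1.8e-60|QDKRAELDAKASQGETVVPGGTGGKSLEAQEHLAEGRSKGGQTRKEQMGT|-1.228",
    "M5.2|LEA5|21|3.4e-36|YQEMGRKGGLSSNDKSGAERAEEEGITID|-1.256",
    "M6.1|DEH|29|2.3e-30|GGGGVAGQEEPEKKGMMDKIKEKLPGGHH|-1.214",
    "M6.2|DEH|29|8.4e-33|GPTTGPPKHRRSGSSSSSSSEDDGMGGRR|-1.679",
    "M6.3|DEH|29|7.2e-37|MAEYGGNYGNETKQTDEYGNPVHHPQGGG|-1.559",
    "M6.4|DEH|21|5.4e-23|KGLKDKIKEKLPGGKKETEPP|-1.710",
    "M7.1|SMP|50|3.5e-60|PQDAATMQAAENSVLGQTQKGGVAATMQSAANRNERAGVVGHNDVTDIIS|-0.402",
    "M7.2|SMP|41|1.3e-48|SAAGDKPVDESDAAAIQAAEARATGLGRVVPGGLGAEAKSA|-0.090")
  f <- strsplit(tab, "|", fixed = TRUE)
  data.frame(name = vapply(f, `[`, "", 1),
             family = vapply(f, `[`, "", 2),
             length_aa = as.integer(vapply(f, `[`, "", 3)),
             evalue = suppressWarnings(as.numeric(vapply(f, `[`, "", 4))),
             consensus = vapply(f, `[`, "", 5),
             gravy_printed = as.numeric(vapply(f, `[`, "", 6)),
             pattern = vapply(f, `[`, "", 5),
             stringsAsFactors = FALSE)
}

#' Parse a bracket pattern into per-position allowed-residue sets
#'
#' `"KKG[_N][MF]M[DE]KIKEK"` parses to one set per position; a set
#' containing `"_"` marks the position optional (matched with the residue
#' present or skipped).
#'
#' @param pattern pattern string
#' @return list with `sets` (list of character vectors) and `optional`
#'   (logical vector)
#' @export
parse_pattern <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  sets <- list(); optional <- logical(0)
  i <- 1
  while (i <= length(chars)) {
    if (chars[i] == "[") {
      j <- i + 1
      grp <- character(0)
      while (j <= length(chars) && chars[j] != "]") {
        grp <- c(grp, chars[j]); j <- j + 1
      }
      if (j > length(chars)) stop("unclosed '[' in pattern: ", pattern)
      opt <- "_" %in% grp
      grp <- setdiff(grp, "_")
      if (length(grp) == 0) stop("empty residue set in pattern: ", pattern)
      sets[[length(sets) + 1]] <- grp
      optional <- c(optional, opt)
      i <- j + 1
    } else {
      sets[[length(sets) + 1]] <- chars[i]
      optional <- c(optional, FALSE)
      i <- i + 1
    }
  }
  list(sets = sets, optional = optional)
}

#' Load the motif registry
#'
#' Returns the built-in 28-motif registry, optionally extended or
#' overridden by a user table (a data frame or TSV path with columns
#' name, family, consensus and optionally pattern, length_aa, evalue,
#' gravy_printed). User rows replace built-ins with the same name.
#'
#' @param config optional data frame or TSV path with extra motifs
#' @return data frame of motif definitions
#' @export
load_registry <- function(config = NULL) {
  reg <- .builtin_motifs()
  if (!is.null(config)) {
    extra <- if (is.character(config))
      utils::read.delim(config, stringsAsFactors = FALSE) else config
    req <- c("name", "family", "consensus")
    if (!all(req %in% names(extra)))
      stop("override table needs columns: ", paste(req, collapse = ", "))
    if (is.null(extra$pattern)) extra$pattern <- extra$consensus
    if (is.null(extra$length_aa)) extra$length_aa <- nchar(extra$consensus)
    if (is.null(extra$evalue)) extra$evalue <- NA_real_
    if (is.null(extra$gravy_printed)) extra$gravy_printed <- NA_real_
    extra <- extra[, c("name", "family", "length_aa", "evalue",
                       "consensus", "gravy_printed", "pattern")]
    for (k in seq_len(nrow(extra))) .validate_motif(extra[k, ])
    reg <- rbind(reg[!(reg$name %in% extra$name), ], extra)
    rownames(reg) <- NULL
  }
  reg
}

# A consensus must be matched by its own pattern at full identity.
.validate_motif <- function(def) {
  p <- parse_pattern(def$pattern)
  cons <- strsplit(def$consensus, "", fixed = TRUE)[[1]]
  n_req <- sum(!p$optional)
  if (length(cons) < n_req || length(cons) > length(p$sets))
    stop("motif '", def$name, "': consensus length ", length(cons),
         " incompatible with pattern (", n_req, "-", length(p$sets),
         " positions)")
  hit <- .match_pattern_at(cons, 1, p)
  if (is.null(hit) || hit$identity < 1)
    stop("motif '", def$name, "': consensus does not match its own pattern")
  invisible(TRUE)
}
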