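#' Motif scanning, dehydrin segments and subgroup assignment
#'
#' Presence/absence of the family consensus motifs is the signal that
#' defines subgroups. Scanning scores each window by per-position identity
#' against the (possibly degenerate) pattern; hits at or above the identity
#' threshold are selected greedily left-to-right without overlap.
#'
#' @name motif_scan
NULL

# Match a parsed pattern against residue vector `r` starting at `pos`,
# trying optional positions both present and absent; returns the best
# (highest-identity, then shortest) variant as list(width, identity), or
# NULL if no variant fits within the sequence.
.match_pattern_at <- function(r, pos, parsed) {
  n_opt <- sum(parsed$optional)
  best <- NULL
  # enumerate subsets of optional positions to include (few in practice)
  opt_idx <- which(parsed$optional)
  for (mask in 0:(2^n_opt - 1)) {
    use <- parsed$sets
    keep <- rep(TRUE, length(use))
    if (n_opt > 0) {
      drop <- opt_idx[bitwAnd(mask, 2^(seq_len(n_opt) - 1)) == 0]
      keep[drop] <- FALSE
    }
    sets <- use[keep]
    w <- length(sets)
    if (w == 0 || pos + w - 1 > length(r)) next
    win <- r[pos:(pos + w - 1)]
    m <- sum(mapply(function(res, set) res %in% set, win, sets))
    ident <- m / w
    if (is.null(best) || ident > best$identity ||
        (ident == best$identity && w < best$width))
      best <- list(width = w, identity = ident)
  }
  best
}

#' Scan one sequence for one motif
#'
#' All non-overlapping windows whose per-position match fraction is at
#' least `min_identity`, chosen greedily left-to-right (candidates ordered
#' by start, ties by higher identity). Optional pattern positions are tried
#' both present and absent; the best-identity variant is kept.
#'
#' @param sequence residue string (or a single-row `proteome_set`)
#' @param motif one row of the registry from [load_registry()]
#' @param min_identity identity threshold in (0, 1]
#' @return data frame of hits: start, end (0-based half-open), start_1based,
#'   end_1based, identity, matched_text
#' @export
scan_motif <- function(sequence, motif, min_identity = 0.8) {
  if (inherits(sequence, "proteome_set")) {
    stopifnot(nrow(sequence) == 1)
    sequence <- sequence$sequence
  }
  stopifnot(min_identity > 0, min_identity <= 1)
  r <- .residues(sequence)
  parsed <- parse_pattern(motif$pattern)
  n <- length(r)
  cands <- list()
  if (!any(parsed$optional)) {
    # fixed-width pattern: score every window with w vectorised compares
    w <- length(parsed$sets)
    if (n >= w) {
      m <- integer(n - w + 1)
      for (j in seq_len(w)) {
        seg <- r[j:(n - w + j)]
        set <- parsed$sets[[j]]
        m <- m + if (length(set) == 1) (seg == set) else (seg %in% set)
      }
      ident <- m / w
      for (pos in which(ident >= min_identity))
        cands[[length(cands) + 1]] <-
          list(start = pos, width = w, identity = ident[pos])
    }
  } else {
    for (pos in seq_len(n)) {
      mt <- .match_pattern_at(r, pos, parsed)
      if (!is.null(mt) && mt$identity >= min_identity)
        cands[[length(cands) + 1]] <-
          list(start = pos, width = mt$width, identity = mt$identity)
    }
  }
  hits <- list()
  if (length(cands) > 0) {
    ord <- order(vapply(cands, `[[`, 0, "start"),
                 -vapply(cands, `[[`, 0, "identity"))
    covered_to <- 0
    for (k in ord) {
      c0 <- cands[[k]]
      if (c0$start > covered_to) {
        hits[[length(hits) + 1]] <- c0
        covered_to <- c0$start + c0$width - 1
      }
    }
  }
  .hits_frame(hits, r, motif$name)
}

.hits_frame <- function(hits, r, label) {
  if (length(hits) == 0)
    return(data.frame(motif = character(), start = integer(),
                      end = integer(), start_1based = integer(),
                      end_1based = integer(), identity = numeric(),
                      matched_text = character(), stringsAsFactors = FALSE))
  s <- vapply(hits, `[[`, 0, "start")
  w <- vapply(hits, `[[`, 0, "width")
  data.frame(motif = label, start = s - 1L, end = s + w - 1L,
             start_1based = s, end_1based = s + w - 1L,
             identity = vapply(hits, `[[`, 0, "identity"),
             matched_text = vapply(seq_along(s), function(i)
               paste(r[s[i]:(s[i] + w[i] - 1)], collapse = ""), ""),
             stringsAsFactors = FALSE)
}

# Dehydrin segment grammars. The K-segment allows one optional N:
# KKG [_N] [MF] M [DE] KIKEK. Y is the exact hexamer; S-segments are
# maximal merged runs of the configured serine-rich patterns.
.k_segment_pattern <- "KKG[_N][MF]M[DE]KIKEK"
.y_segment <- "DEYGNP"
.s_patterns_default <- c("SGSSSSSSS", "TGSSSSSS", "SSSSSSS", "SSSSSSSS")

# all (possibly overlapping) literal match intervals via lookahead
.literal_matches <- function(sequence, pat) {
  m <- gregexpr(paste0("(?=", pat, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1) return(NULL)
  cbind(start = as.integer(m), end = as.integer(m) + nchar(pat) - 1L)
}

#' Detect dehydrin K-, Y- and S-segments
#'
#' K-hits follow the grammar KKG, optional N, one of M/F, M, one of D/E,
#' then KIKEK, contiguously. Y-hits are exact DEYGNP matches. S-hits are
#' maximal hits after merging overlapping matches of the serine-run
#' patterns (defaults: SGSSSSSSS, TGSSSSSS, S7, S8).
#'
#' @param sequence residue string (or a single-row `proteome_set`)
#' @param s_patterns literal S-segment patterns to merge
#' @return data frame: kind (K/Y/S), start, end (0-based half-open),
#'   start_1based, end_1based, matched_text
#' @export
detect_dehydrin_segments <- function(sequence,
                                     s_patterns = .s_patterns_default) {
  if (inherits(sequence, "proteome_set")) {
    stopifnot(nrow(sequence) == 1)
    sequence <- sequence$sequence
  }
  r <- .residues(sequence)
  out <- list()
  add <- function(kind, start, end) {  # 1-based inclusive in, both out
    out[[length(out) + 1]] <<- data.frame(
      kind = kind, start = start - 1L, end = end,
      start_1based = start, end_1based = end,
      matched_text = substr(sequence, start, end),
      stringsAsFactors = FALSE)
  }
  # K: expand the optional position into two literal regex branches
  km <- gregexpr("(?=(KKGN?[MF]M[DE]KIKEK))", sequence, perl = TRUE)[[1]]
  if (km[1] != -1) {
    lens <- attr(km, "capture.length")[, 1]
    for (i in seq_along(km)) add("K", as.integer(km[i]),
                                 as.integer(km[i]) + lens[i] - 1L)
  }
  ym <- .literal_matches(sequence, .y_segment)
  if (!is.null(ym)) for (i in seq_len(nrow(ym))) add("Y", ym[i, 1], ym[i, 2])
  # S: union of all pattern matches, merged into maximal intervals
  iv <- do.call(rbind, lapply(s_patterns, .literal_matches, sequence = sequence))
  if (!is.null(iv) && nrow(iv) > 0) {
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    cur <- iv[1, ]
    flush <- function(c0) add("S", c0[[1]], c0[[2]])
    if (nrow(iv) > 1) {
      for (i in 2:nrow(iv)) {
        if (iv[i, 1] <= cur[[2]] + 1) cur[[2]] <- max(cur[[2]], iv[i, 2])
        else { flush(cur); cur <- iv[i, ] }
      }
    }
    flush(cur)
  }
  if (length(out) == 0)
    return(data.frame(kind = character(), start = integer(), end = integer(),
                      start_1based = integer(), end_1based = integer(),
                      matched_text = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Motif presence profile of one sequence
#'
#' Names of registry motifs with at least one hit at the given identity.
#'
#' @param sequence residue string (or single-row `proteome_set`)
#' @param registry data frame from [load_registry()]
#' @param min_identity identity threshold
#' @return character vector of motif names
#' @export
motif_presence_profile <- function(sequence, registry = load_registry(),
                                   min_identity = 0.8) {
  present <- vapply(seq_len(nrow(registry)), function(i)
    nrow(scan_motif(sequence, registry[i, ], min_identity)) > 0, logical(1))
  registry$name[present]
}

# Subgroup rule table, most-specific (largest required set) first within
# each family. `absent` lists motifs that must NOT be present.
.subgroup_rules <- list(
  LEA1 = list(list(req = c("M1.1", "M1.2"), label = "LEA1.1"),
              list(req = "M1.1", label = "LEA1.2"),
              list(req = "M1.2", label = "LEA1.3")),
  LEA2 = list(list(req = c("M2.1", "M2.2", "M2.6", "M2.3", "M2.5"),
                   label = "LEA2.1"),
              list(req = c("M2.1", "M2.2", "M2.6"), label = "LEA2.2"),
              list(req = "M2.4", label = "LEA2.3"),
              list(req = "M2.8", label = "LEA2.5"),
              list(req = "M2.9", label = "LEA2.4")),
  LEA3 = list(list(req = "M3.4", label = "LEA3.2"),
              list(req = "M3.1", label = "LEA3.1"),
              list(req = "M3.2", label = "LEA3.1"),
              list(req = "M3.3", label = "LEA3.1"),
              list(req = "M3.5", label = "LEA3.1")),
  LEA4 = list(list(req = "M4.3", label = "LEA4.1"),
              list(req = "M4.2", label = "LEA4.2"),
              list(req = "M4.1", label = "LEA4.3"),
              list(req = "M4.4", label = "LEA4.3")),
  LEA5 = list(list(req = "M5.1", label = "LEA5"),
              list(req = "M5.2", label = "LEA5")),
  DEH  = list(list(req = "M6.3", label = "DEH1"),
              list(req = "M6.1", label = "DEH2"),
              list(req = "M6.2", label = "DEH2"),
              list(req = "M6.4", label = "DEH2")),
  SMP  = list(list(req = c("M7.1", "M7.2"), label = "SMP3"),
              list(req = "M7.1", label = "SMP2"),
              list(req = "M7.2", label = "SMP1")))

#' Assign a motif-architecture subgroup
#'
#' Deterministic rule-table evaluation: within a family, rules are checked
#' in a documented precedence order (largest required motif set first, so
#' the "extended" LEA2.1 wins over LEA2.2; the DEH1-determining M6.3 wins
#' over the shared dehydrin motifs; SMP3 = both SMP motifs, SMP2 = M7.1
#' only, SMP1 = M7.2 only). LEA5 has no printed subdivisions and keeps the
#' plain family label when any LEA5 motif is present. If no rule fires the
#' label is `"<family>.0"`.
#'
#' @param family one of LEA1..LEA5, DEH, SMP
#' @param present character vector of motif names present
#' @return subgroup label (character)
#' @export
assign_subgroup <- function(family, present) {
  if (!family %in% names(.subgroup_rules))
    stop("unknown family: ", family)
  for (rule in .subgroup_rules[[family]])
    if (all(rule$req %in% present)) return(rule$label)
  paste0(family, ".0")
}
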