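# Motif registry, scanning, dehydrin segments, subgroup assignment

test_that("default registry holds all 28 motifs with consistent fields", {
  reg <- load_registry()
  expect_equal(nrow(reg), 28)
  expect_setequal(unique(reg$family),
                  c("LEA1", "LEA2", "LEA3", "LEA4", "LEA5", "DEH", "SMP"))
  m12 <- reg[reg$name == "M1.2", ]
  expect_equal(m12$length_aa, 21)
  expect_equal(m12$consensus, "MQAAKETAANVAASANSGMEK")
  # printed length and string length agree for every row except the known
  # M5.2 misprint (string taken as authoritative)
  mismatch <- reg$name[nchar(reg$consensus) != reg$length_aa]
  expect_equal(mismatch, "M5.2")
})

test_that("registry can be extended and validates overrides", {
  reg <- load_registry(data.frame(name = "MX", family = "LEA1",
                                  consensus = "A", stringsAsFactors = FALSE))
  expect_true("MX" %in% reg$name)
  expect_equal(nrow(reg), 29)
  expect_error(
    load_registry(data.frame(name = "MBAD", family = "LEA1",
                             consensus = "AAA", pattern = "GGG",
                             stringsAsFactors = FALSE)),
    "does not match its own pattern")
})

test_that("pattern parsing handles literals, choices and optional positions", {
  p <- parse_pattern("KKG[_N][MF]M[DE]KIKEK")
  expect_length(p$sets, 12)  # KKG + [_N] + [MF] + M + [DE] + KIKEK
  expect_equal(p$optional, c(rep(FALSE, 3), TRUE, rep(FALSE, 8)))
  expect_equal(p$sets[[4]], "N")
  expect_equal(p$sets[[5]], c("M", "F"))
  expect_error(parse_pattern("A[BC"), "unclosed")
})

test_that("every motif's own consensus yields exactly one full-identity self-hit", {
  reg <- load_registry()
  for (i in seq_len(nrow(reg))) {
    hits <- scan_motif(reg$consensus[i], reg[i, ], min_identity = 0.8)
    expect_equal(nrow(hits), 1, info = reg$name[i])
    expect_equal(hits$identity, 1, info = reg$name[i])
    expect_equal(hits$start, 0, info = reg$name[i])
    expect_equal(hits$end, nchar(reg$consensus[i]), info = reg$name[i])
  }
})

test_that("scanning matches the exhaustive-window oracle on random sequences", {
  reg <- load_registry()
  withr::local_seed(31)
  m <- reg[reg$name == "M6.4", ]  # 21-residue literal pattern
  for (i in 1:10) {
    # plant a degraded copy (a few mutations) into a random background
    s <- random_seq(120)
    cons <- strsplit(m$consensus, "")[[1]]
    mut <- sample(21, sample(0:5, 1))
    cons[mut] <- sample(names(KD_ORACLE), length(mut), replace = TRUE)
    pos <- sample(1:(120 - 21), 1)
    s <- paste0(substr(s, 1, pos - 1), paste(cons, collapse = ""),
                substr(s, pos + 21, 120))
    got <- scan_motif(s, m, min_identity = 0.8)
    want <- oracle_scan_literal(s, m$consensus, 0.8)
    expect_equal(got$start_1based, want$start)
    expect_equal(got$identity, want$identity)
  }
})

test_that("poly-A matches nothing at the default threshold", {
  reg <- load_registry()
  m11 <- reg[reg$name == "M1.1", ]
  expect_equal(nrow(scan_motif(strrep("A", 200), m11)), 0)
})

test_that("dehydrin segment grammars fire as described on the consensus motifs", {
  reg <- load_registry()
  cons <- function(n) reg$consensus[reg$name == n]
  k <- detect_dehydrin_segments(cons("M6.1"))
  expect_equal(k$kind, "K")
  expect_equal(k$matched_text, "KKGMMDKIKEK")
  y <- detect_dehydrin_segments(cons("M6.3"))
  expect_equal(y$kind, "Y")
  expect_equal(c(y$start, y$end), c(15, 21))  # 0-based half-open
  expect_equal(y$matched_text, "DEYGNP")
  s <- detect_dehydrin_segments(cons("M6.2"))
  expect_equal(s$kind, "S")
  expect_match(s$matched_text, "SGSSSSSSS", fixed = TRUE)
  expect_equal(nrow(s), 1)  # overlapping S-patterns merge into one hit
  # M6.4 carries K-segment-like text but lacks the KKG prefix: the strict
  # grammar must not fire
  expect_equal(nrow(detect_dehydrin_segments(cons("M6.4"))), 0)
})

test_that("K-segment optional position matches with and without the N", {
  base <- paste0(strrep("G", 10), "KKGMMEKIKEK", strrep("G", 10))
  with_n <- paste0(strrep("G", 10), "KKGNMMDKIKEK", strrep("G", 10))
  k1 <- detect_dehydrin_segments(base)
  k2 <- detect_dehydrin_segments(with_n)
  expect_equal(k1$matched_text, "KKGMMEKIKEK")
  expect_equal(k2$matched_text, "KKGNMMDKIKEK")
})

test_that("alternative S-segment spellings are detected and merged maximally", {
  s <- detect_dehydrin_segments(paste0("AAAA", "TGSSSSSS", "AAAA"))
  expect_equal(s$matched_text, "TGSSSSSS")
  # a long serine run yields one maximal hit, not several overlapping ones
  s8 <- detect_dehydrin_segments(paste0("AAAA", strrep("S", 12), "AAAA"))
  expect_equal(nrow(s8), 1)
  expect_equal(s8$matched_text, strrep("S", 12))
})

test_that("presence profile composes scan_motif over the registry", {
  reg <- load_registry()
  s <- paste0(reg$consensus[reg$name == "M1.1"], strrep("G", 10),
              reg$consensus[reg$name == "M1.2"])
  expect_setequal(motif_presence_profile(s, reg[reg$family == "LEA1", ]),
                  c("M1.1", "M1.2"))
  expect_length(motif_presence_profile(strrep("G", 100), reg), 0)
  # compositional oracle on a dehydrin-architecture sequence
  s2 <- paste0(reg$consensus[reg$name == "M6.3"], strrep("G", 5),
               reg$consensus[reg$name == "M6.1"])
  got <- motif_presence_profile(s2, reg)
  direct <- reg$name[vapply(seq_len(nrow(reg)), function(i)
    nrow(scan_motif(s2, reg[i, ])) > 0, logical(1))]
  expect_setequal(got, direct)
})

test_that("subgroup assignment follows the published motif architectures", {
  expect_equal(assign_subgroup("LEA1", c("M1.1", "M1.2")), "LEA1.1")
  expect_equal(assign_subgroup("LEA1", "M1.1"), "LEA1.2")
  expect_equal(assign_subgroup("LEA1", "M1.2"), "LEA1.3")
  expect_equal(assign_subgroup("LEA2", character(0)), "LEA2.0")
  expect_equal(assign_subgroup("LEA2", c("M2.1", "M2.2", "M2.6")), "LEA2.2")
  expect_equal(
    assign_subgroup("LEA2", c("M2.1", "M2.2", "M2.6", "M2.3", "M2.5")),
    "LEA2.1")  # extended set wins over LEA2.2
  expect_equal(assign_subgroup("LEA2", c("M2.4", "M2.6")), "LEA2.3")
  expect_equal(assign_subgroup("LEA2", c("M2.9", "M2.6")), "LEA2.4")
  expect_equal(assign_subgroup("LEA2", "M2.8"), "LEA2.5")
  expect_equal(assign_subgroup("DEH", c("M6.1", "M6.3")), "DEH1")
  expect_equal(assign_subgroup("DEH", "M6.1"), "DEH2")
  expect_equal(assign_subgroup("LEA4", c("M4.1", "M4.3")), "LEA4.1")
  expect_equal(assign_subgroup("LEA4", c("M4.1", "M4.2")), "LEA4.2")
  expect_equal(assign_subgroup("LEA4", "M4.1"), "LEA4.3")
  expect_equal(assign_subgroup("SMP", c("M7.1", "M7.2")), "SMP3")
  expect_equal(assign_subgroup("SMP", "M7.1"), "SMP2")
  expect_equal(assign_subgroup("LEA5", "M5.1"), "LEA5")
  expect_error(assign_subgroup("LEA9", "M1.1"), "unknown family")
  # pure function: repeated evaluation is stable
  expect_equal(assign_subgroup("DEH", c("M6.1", "M6.3")),
               assign_subgroup("DEH", c("M6.1", "M6.3")))
})
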