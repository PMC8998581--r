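# Family classification from domain annotations and family summaries

test_that("accession map covers the seven families and rejects nothing", {
  expect_equal(map_domain_to_family("PF03760"), "LEA1")
  expect_equal(map_domain_to_family("PF03168"), "LEA2")
  expect_equal(map_domain_to_family("PF03242"), "LEA3")
  expect_equal(map_domain_to_family("PF02987"), "LEA4")
  expect_equal(map_domain_to_family("PF00477"), "LEA5")
  expect_equal(map_domain_to_family("PF00257"), "DEH")
  expect_equal(map_domain_to_family("PF04927"), "SMP")
  expect_equal(map_domain_to_family("PF99999"), "unclassified")
  # vectorised
  expect_equal(map_domain_to_family(c("PF03760", "PFX")),
               c("LEA1", "unclassified"))
})

test_that("classification composes length filter, domain and motif stages", {
  reg <- load_registry()
  m42 <- reg$consensus[reg$name == "M4.2"]
  m41 <- reg$consensus[reg$name == "M4.1"]
  withr::local_seed(71)
  seqs <- c(
    lea4 = paste0(random_seq(40), m41, random_seq(10), m42, random_seq(40)),
    short = random_seq(80),
    nodom = random_seq(150),
    weak = random_seq(150))
  set <- proteome_set(names(seqs), seqs, source = "synthetic")
  ann <- data.frame(
    protein_id = c("lea4", "short", "weak"),
    pfam_id = c("PF02987", "PF02987", "PF02987"),
    evalue = c(1e-10, 1e-10, 1e-3),  # 'weak' fails the 1e-5 threshold
    stringsAsFactors = FALSE)
  cls <- classify_proteome(set, ann, reg)
  expect_false("short" %in% cls$id)  # dropped by length regardless of domain
  expect_equal(cls$family[cls$id == "lea4"], "LEA4")
  expect_equal(cls$subgroup[cls$id == "lea4"], "LEA4.2")
  expect_equal(cls$family[cls$id == "nodom"], "unclassified")
  expect_equal(cls$family[cls$id == "weak"], "unclassified")
  expect_error(classify_proteome(set, data.frame(
    protein_id = "ghost", pfam_id = "PF02987", evalue = 1e-9)),
    "unknown protein id")
})

test_that("classification equals applying each stage separately", {
  gp <- generate_proteome(counts = c(LEA1 = 4, DEH = 4, SMP = 4), seed = 73)
  reg <- load_registry()
  cls <- classify_proteome(gp$set, gp$annotations, reg)
  kept <- filter_by_length(gp$set, 100, quiet = TRUE)
  for (i in seq_len(nrow(kept))) {
    id <- kept$id[i]
    ann <- gp$annotations[gp$annotations$protein_id == id &
                          gp$annotations$evalue <= 1e-5, ]
    fam <- map_domain_to_family(ann$pfam_id[which.min(ann$evalue)])
    present <- motif_presence_profile(kept$sequence[i],
                                      reg[reg$family == fam, ])
    expect_equal(cls$family[cls$id == id], fam)
    expect_equal(cls$subgroup[cls$id == id], assign_subgroup(fam, present))
  }
})

test_that("multi-domain proteins take the lowest e-value", {
  withr::local_seed(79)
  set <- proteome_set("p1", random_seq(150), source = "synthetic")
  ann <- data.frame(protein_id = c("p1", "p1"),
                    pfam_id = c("PF03760", "PF00477"),
                    evalue = c(1e-6, 1e-12), stringsAsFactors = FALSE)
  cls <- classify_proteome(set, ann)
  expect_equal(cls$family, "LEA5")
})

test_that("family counts are conserved and monotone in the e-value cutoff", {
  gp <- generate_proteome(counts = c(LEA1 = 5, LEA2 = 5, LEA5 = 5), seed = 83)
  cls <- classify_proteome(gp$set, gp$annotations)
  expect_equal(nrow(cls), nrow(filter_by_length(gp$set, 100, quiet = TRUE)))
  counts_at <- function(e) {
    cl <- classify_proteome(gp$set, gp$annotations, evalue_max = e)
    table(factor(cl$family, levels = c("LEA1", "LEA2", "LEA5")))
  }
  loose <- counts_at(1e-5)
  tight <- counts_at(1e-12)  # below the generated 1e-10
  expect_true(all(tight <= loose))
})

test_that("family_summary means and SEs match brute-force arithmetic", {
  gp <- generate_proteome(counts = c(LEA1 = 8, DEH = 8), seed = 89)
  cls <- classify_proteome(gp$set, gp$annotations)
  ph <- physchem_table(gp$set)
  fs <- family_summary(cls, ph, variables = c("gravy", "pi"))
  for (v in c("gravy", "pi")) {
    tab <- fs[[v]]
    for (f in tab$family) {
      ids <- cls$id[cls$family == f]
      x <- ph[[v]][match(ids, ph$id)]
      expect_equal(tab$mean[tab$family == f], mean(x))
      expect_equal(tab$se[tab$family == f], sd(x) / sqrt(length(x)))
      expect_equal(tab$n[tab$family == f], length(x))
    }
  }
})

test_that("identical groups share a letter; distinct groups are separated", {
  # two families with literally identical members must share a letter
  ph <- data.frame(id = sprintf("p%d", 1:8),
                   gravy = rep(c(-1, -1.1, -0.9, -1), 2))
  cls <- data.frame(id = ph$id,
                    family = rep(c("LEA1", "LEA5"), each = 4),
                    stringsAsFactors = FALSE)
  fs <- family_summary(cls, ph, variables = "gravy")
  expect_equal(fs$gravy$group[1], fs$gravy$group[2])
  # strongly separated families get different letters
  ph2 <- data.frame(id = sprintf("q%d", 1:12),
                    gravy = c(rnorm(6, -1.4, 0.01), rnorm(6, 0, 0.01)))
  cls2 <- data.frame(id = ph2$id,
                     family = rep(c("DEH", "LEA2"), each = 6),
                     stringsAsFactors = FALSE)
  fs2 <- family_summary(cls2, ph2, variables = "gravy")
  expect_false(fs2$gravy$group[1] == fs2$gravy$group[2])
  # singleton family: SE missing, excluded from post hoc
  ph3 <- rbind(ph2, data.frame(id = "solo", gravy = -0.5))
  cls3 <- rbind(cls2, data.frame(id = "solo", family = "SMP"))
  fs3 <- family_summary(cls3, ph3, variables = "gravy")
  expect_true(is.na(fs3$gravy$se[fs3$gravy$family == "SMP"]))
  expect_true(is.na(fs3$gravy$group[fs3$gravy$family == "SMP"]))
})
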