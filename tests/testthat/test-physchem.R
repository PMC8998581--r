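# Physicochemical profiling: GRAVY, MW, pI, composition, charge,
# hydrophilin criterion

test_that("GRAVY reproduces the consensus-motif reference values", {
  # absolute tolerance: the reference values are printed to 3 decimals
  expect_lt(abs(gravy("MQAAKETAANVAASANSGMEK") - (-0.352)), 0.0005)
  expect_lt(abs(
    gravy("TKATVQEKAEQMKTRDPLQKEMATQKKEAKIQEAERQKQEARQQNSAAKH") -
      (-1.786)), 0.0005)
  expect_equal(gravy("AAAA"), 1.8)
  expect_error(gravy("AAAA", scale = c(G = 1)), "absent from scale")
})

test_that("GRAVY of a concatenation is the length-weighted mean of parts", {
  withr::local_seed(7)
  for (i in 1:10) {
    a <- random_seq(sample(5:60, 1))
    b <- random_seq(sample(5:60, 1))
    expect_equal(
      gravy(paste0(a, b)),
      (gravy(a) * nchar(a) + gravy(b) * nchar(b)) / (nchar(a) + nchar(b)))
  }
})

test_that("hydropathy profile equals the brute-force sliding mean", {
  withr::local_seed(11)
  for (i in 1:5) {
    s <- random_seq(60)
    w <- sample(c(3, 9, 19), 1)
    prof <- hydropathy_profile(s, w)
    expect_equal(prof$value, unname(oracle_sliding_mean(s, w)))
    expect_equal(prof$position, seq_len(60 - w + 1) + (w - 1) %/% 2)
  }
  s <- random_seq(21)
  expect_equal(hydropathy_profile(s, 21)$value, gravy(s))
  expect_error(hydropathy_profile("AAA", 5), "exceeds sequence length")
  expect_error(hydropathy_profile(random_seq(20), 4), "odd")
})

test_that("molecular weight follows residue masses plus one water", {
  expect_equal(molecular_weight("G"), 0.0750672, tolerance = 1e-7)
  expect_equal(molecular_weight("GG") - molecular_weight("G"),
               0.0570519, tolerance = 1e-7)
  # additivity over arbitrary residues
  withr::local_seed(3)
  s <- random_seq(40)
  expect_equal(molecular_weight(paste0(s, "W")) - molecular_weight(s),
               0.1862132, tolerance = 1e-7)
})

test_that("pI matches a fine-grid charge-curve scan within 0.01", {
  withr::local_seed(2024)
  for (i in 1:20) {
    s <- random_seq(100)
    expect_equal(isoelectric_point(s), oracle_pi_grid(s), tolerance = 0.01)
  }
})

test_that("pI behaves like a pI: zero charge at root, basic > acidic, composition-only", {
  withr::local_seed(5)
  for (i in 1:5) {
    s <- random_seq(80)
    expect_lt(abs(oracle_charge(s, isoelectric_point(s))), 0.01)
    # composition-only up to the N-terminal residue, whose identity sets
    # the alpha-amino pK (ProtParam convention): permute all but the first
    r <- strsplit(s, "")[[1]]
    sh <- paste(c(r[1], sample(r[-1])), collapse = "")
    expect_equal(isoelectric_point(sh), isoelectric_point(s),
                 tolerance = 0.002)
  }
  expect_gt(isoelectric_point(strrep("K", 25)),
            isoelectric_point(strrep("D", 25)))
})

test_that("composition and category percents match brute-force counting", {
  cc <- composition_and_categories("GGGG")
  expect_equal(cc$composition[["G"]], 1)
  expect_equal(sum(cc$composition), 1)
  expect_equal(unname(cc$category_pct["charged"]), 0)
  expect_equal(unname(cc$category_pct["nonpolar"]), 100)  # G is nonpolar
  withr::local_seed(13)
  sch <- category_scheme()
  for (i in 1:5) {
    s <- random_seq(70)
    r <- strsplit(s, "")[[1]]
    cc <- composition_and_categories(s, sch)
    expect_equal(sum(cc$composition), 1, tolerance = 1e-9)
    for (k in names(sch))
      expect_equal(unname(cc$category_pct[k]),
                   100 * sum(r %in% sch[[k]]) / length(r))
    expect_true(all(cc$category_pct >= 0 & cc$category_pct <= 100))
  }
})

test_that("net formal charge counts K,R minus D,E; His optional", {
  # 20-residue window: 4 Lys, 1 Arg, 1 Glu, 1 Asp, 13 neutral -> +3
  expect_equal(net_formal_charge("KKKKREDGGGGGGGGGGGGL"), 3)
  expect_equal(net_formal_charge(strrep("G", 30)), 0)
  expect_equal(net_formal_charge("HHHH"), 0)
  expect_equal(net_formal_charge("HHHH", include_his = TRUE), 4)
  withr::local_seed(17)
  for (i in 1:5) {
    s <- random_seq(50)
    r <- strsplit(s, "")[[1]]
    expect_equal(net_formal_charge(s),
                 sum(r %in% c("K", "R")) - sum(r %in% c("D", "E")))
  }
})

test_that("hydrophilin criterion is strict on both thresholds", {
  expect_true(is_hydrophilin(gly_pct = 8, gravy = -1.4))
  expect_false(is_hydrophilin(gly_pct = 6.0, gravy = -1.4))  # boundary
  expect_false(is_hydrophilin(gly_pct = 0, gravy = 1.8))     # poly-A
  expect_false(is_hydrophilin(gly_pct = 8, gravy = -1.0))    # boundary
  # printed-text preset: GRAVY < 1 admits mildly hydrophobic proteins too
  expect_true(is_hydrophilin(gly_pct = 8, gravy = 0.5, gravy_max = 1))
})

test_that("physchem and scatter tables are row-per-protein and self-consistent", {
  withr::local_seed(23)
  set <- proteome_set(sprintf("p%d", 1:6),
                      vapply(1:6, function(i) random_seq(120), ""),
                      source = "synthetic")
  tab <- physchem_table(set)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$id, set$id)
  panels <- gly_gravy_table(set)
  expect_named(panels, c("gly", "lys_glu", "ala", "ile_leu_val", "cys",
                         "trp", "his", "pro"))
  expect_equal(nrow(panels$gly), 6)
  # flags agree with applying the criterion row-wise
  expect_equal(panels$gly$hydrophilin,
               is_hydrophilin(tab$pct_gly, tab$gravy))
  expect_equal(panels$gly$pct, tab$pct_gly)
  # empty set -> empty tables
  empty <- set[0, ]
  expect_equal(nrow(physchem_table(empty)), 0)
  expect_equal(nrow(gly_gravy_table(empty)$gly), 0)
})
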