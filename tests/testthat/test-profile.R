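# build a template directly from a toy structure whose pocket is planted
planted_template <- function(seq, planted, cutoff = 6) {
  m <- parse_structure(make_toy_structure(nchar(seq), planted, cutoff))
  pocket <- extract_pocket(m, select_ligands(m), cutoff)
  build_template(list(pocket), seq, ids = "T1")
}

test_that("a single-template active site is just the pocket positions", {
  set.seed(41)
  seq <- random_seq(30)
  tmpl <- planted_template(seq, c(3, 7, 9))
  expect_equal(nrow(tmpl$positions), 3)
  expect_equal(tmpl$positions$pos, c(3, 7, 9))
  expect_equal(paste(tmpl$positions$residue, collapse = ""),
               paste(substring(seq, c(3, 7, 9), c(3, 7, 9)), collapse = ""))
})

test_that("the union of two identical templates is idempotent", {
  set.seed(43)
  seq <- random_seq(40)
  m <- parse_structure(make_toy_structure(40, c(5, 12, 20, 33)))
  pocket <- extract_pocket(m, select_ligands(m))
  tmpl <- build_template(list(pocket, pocket), c(seq, seq),
                         ids = c("T1", "T2"))
  expect_equal(nrow(tmpl$positions), 4)
  expect_true(all(grepl("T1\\+T2", tmpl$positions$sources)))
})

test_that("union size is bounded by the individual pockets", {
  set.seed(47)
  for (rep in 1:5) {
    seq1 <- random_seq(50)
    # second template: same length, moderately diverged
    seq2 <- local({
      ch <- strsplit(seq1, "")[[1]]
      idx <- sample(50, 12)
      ch[idx] <- vapply(ch[idx], function(a)
        sample(setdiff(pocketprofile:::AA20, a), 1), character(1))
      paste(ch, collapse = "")
    })
    p1 <- sort(sample(50, 8))
    p2 <- sort(sample(50, 6))
    m1 <- parse_structure(make_toy_structure(50, p1))
    m2 <- parse_structure(make_toy_structure(50, p2))
    pk1 <- extract_pocket(m1, select_ligands(m1))
    pk2 <- extract_pocket(m2, select_ligands(m2))
    tmpl <- build_template(list(pk1, pk2), c(seq1, seq2), c("T1", "T2"))
    expect_gte(nrow(tmpl$positions), max(length(p1), length(p2)))
    expect_lte(nrow(tmpl$positions), length(p1) + length(p2))
  }
})

test_that("projecting the template sequence round-trips the pocket residues", {
  set.seed(53)
  for (rep in 1:5) {
    seq <- random_seq(35)
    planted <- sort(sample(35, 6))
    tmpl <- planted_template(seq, planted)
    prof <- project_profile(seq, tmpl)
    expect_equal(prof$residues,
                 paste(strsplit(seq, "")[[1]][planted], collapse = ""))
  }
})

test_that("a pocket-position substitution changes exactly that profile character", {
  set.seed(59)
  seq <- random_seq(30)
  planted <- c(4, 11, 18, 25)
  tmpl <- planted_template(seq, planted)
  mutated <- seq
  orig <- substr(mutated, 11, 11)
  substr(mutated, 11, 11) <- sample(setdiff(pocketprofile:::AA20, orig), 1)
  p_ref <- project_profile(seq, tmpl)
  p_mut <- project_profile(mutated, tmpl)
  diff <- which(strsplit(p_ref$residues, "")[[1]] !=
                  strsplit(p_mut$residues, "")[[1]])
  expect_equal(diff, 2L)  # position 11 is the 2nd template position
  pid <- profile_identity(p_ref, p_mut)
  expect_equal(pid$identical_count, 3)
  expect_equal(pid$comparable_count, 4)
})

test_that("a deleted motif region projects as gaps and fails completeness", {
  set.seed(61)
  base <- random_seq(60)
  substring(base, 20, 24) <- "DDLTD"
  substring(base, 40, 48) <- "NDTASLLVE"
  planted <- c(20:24, 40:48)
  tmpl <- planted_template(base, planted)
  # delete the NSE-triad region from the query
  query <- paste0(substr(base, 1, 39), substr(base, 49, 60))
  prof <- project_profile(query, tmpl)
  chars <- strsplit(prof$residues, "")[[1]]
  expect_true(all(chars[6:14] == "-"))
  expect_true(all(chars[1:5] != "-"))
  expect_false(motif_complete(query))
  expect_true(motif_complete(base))
})

test_that("profile identity counts comparable positions and rounds half-up", {
  mk <- function(id, res) structure(
    list(enzyme_id = id, residues = res, template = "T:4"),
    class = "active_site_profile")
  pid <- profile_identity(mk("a", "DDLE"), mk("b", "DDLQ"))
  expect_equal(pid$identical_count, 3)
  expect_equal(pid$percentage, 75)
  # gaps reduce the comparable denominator, not identity
  pid2 <- profile_identity(mk("a", "DDL-"), mk("b", "DDLQ"))
  expect_equal(pid2$comparable_count, 3)
  expect_equal(pid2$percentage, 100)
  expect_equal(pid2$percentage_full_denominator, 75)
  # the 36-of-38 convention reports 95%
  a38 <- paste(rep("A", 38), collapse = "")
  b38 <- paste(c(rep("A", 36), "C", "C"), collapse = "")
  mk38 <- function(id, r) structure(
    list(enzyme_id = id, residues = r, template = "T:38"),
    class = "active_site_profile")
  pid38 <- profile_identity(mk38("x", a38), mk38("y", b38))
  expect_equal(pid38$identical_count, 36)
  expect_equal(pid38$percentage_rounded, 95)
  # mismatched templates refuse to compare
  expect_error(profile_identity(mk("a", "DDLE"), mk38("x", a38)),
               "incompatible")
})

test_that("profile identity is symmetric and equals a brute-force count", {
  set.seed(67)
  seq <- random_seq(40)
  tmpl <- planted_template(seq, sort(sample(40, 10)))
  q1 <- random_seq(40)
  q2 <- random_seq(40)
  p1 <- project_profile(q1, tmpl)
  p2 <- project_profile(q2, tmpl)
  pid12 <- profile_identity(p1, p2)
  pid21 <- profile_identity(p2, p1)
  expect_equal(pid12$percentage, pid21$percentage)
  c1 <- strsplit(p1$residues, "")[[1]]
  c2 <- strsplit(p2$residues, "")[[1]]
  brute <- sum(c1 == c2 & c1 != "-" & c2 != "-")
  expect_equal(pid12$identical_count, brute)
})

test_that("motif scanning matches the naive sliding-window oracle", {
  expect_equal(scan_motifs("DDAAD")$start, 1)
  expect_equal(scan_motifs("DDAAD")$motif, "aspartate_rich")
  nse <- scan_motifs("NDVLSAAAE")
  expect_equal(nse$motif, "nse_triad")
  expect_equal(nse$start, 1)
  none <- scan_motifs("AAAA")
  expect_equal(nrow(none), 0)
  expect_false(attr(none, "complete"))

  # property check against the oracle on motif-enriched random sequences
  set.seed(71)
  alphabet <- c("D", "D", "E", "N", "S", "T", "A", "L", "G", "V")
  for (i in 1:1000) {
    s <- random_seq(sample(9:40, 1), alphabet)
    got <- scan_motifs(s)
    want <- oracle_motifs(s)
    expect_equal(got[, c("motif", "start")],
                 want[order(match(want$motif, c("aspartate_rich", "nse_triad")),
                            want$start), ],
                 ignore_attr = TRUE)
  }
})

test_that("function prediction labels by nearest conserved active site", {
  set.seed(73)
  base <- random_seq(60)
  substring(base, 20, 24) <- "DDLTD"
  substring(base, 35, 43) <- "NDTASLLVE"
  planted <- c(20:24, 35:43, 50:55)
  tmpl <- planted_template(base, planted)

  refs <- data.frame(
    id = c("lns_ref", "cad_ref"),
    sequence = c(base, local({
      s <- base
      # diverge the cadinene reference outside the motifs
      idx <- setdiff(seq(2, 58, by = 3), c(20:24, 35:43))
      ch <- strsplit(s, "")[[1]]
      ch[idx] <- vapply(ch[idx], function(a)
        sample(setdiff(pocketprofile:::AA20, a), 1), character(1))
      paste(ch, collapse = "")
    })),
    label = c("linalool synthase", "muurolene/cadinene synthase")
  )

  # an exact copy of a reference gets its label at 100%
  calls <- predict_function(c(q1 = base), refs, tmpl)
  expect_equal(calls$predicted_label, "linalool synthase")
  expect_equal(calls$active_site_identity, 100)
  expect_true(calls$motif_complete)

  # a query nearest the cadinene reference is called cadinene
  calls2 <- predict_function(c(q2 = refs$sequence[2]), refs, tmpl)
  expect_equal(calls2$predicted_label, "muurolene/cadinene synthase")

  # high identity but missing NSE triad -> unassigned with evidence
  broken <- base
  substring(broken, 35, 43) <- "AAAAAAAAA"
  calls3 <- predict_function(c(q3 = broken), refs, tmpl)
  expect_equal(calls3$predicted_label, "unassigned")
  expect_match(calls3$evidence, "incomplete pocket")
  expect_error(predict_function(c(q = base), refs[0, ], tmpl), "references")
})

test_that("profiles serialize as aligned FASTA", {
  set.seed(79)
  seq <- random_seq(30)
  tmpl <- planted_template(seq, c(2, 9, 17))
  profs <- list(project_profile(seq, tmpl, query_id = "a"),
                project_profile(random_seq(30), tmpl, query_id = "b"))
  tf <- tempfile(fileext = ".afa")
  write_profiles_fasta(profs, tf)
  got <- read_fasta(tf)
  expect_equal(names(got), c("a", "b"))
  expect_equal(nchar(got[["a"]]), 3)
})
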