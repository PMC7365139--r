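test_that("pre-sequences have the declared length, alphabet and GC bias", {
  pres <- generate_presequences(10000, seed = 3)
  expect_true(all(nchar(pres) == 15))
  expect_false(any(grepl("[^ACGT]", pres)))
  gc <- mean(vapply(
    strsplit(pres, ""),
    function(ch) mean(ch %in% c("G", "C")), numeric(1)
  ))
  expect_gte(gc, 0.38)
  expect_lte(gc, 0.42)
  expect_identical(pres, generate_presequences(10000, seed = 3))
  expect_error(generate_presequences(0))
})

test_that("promoter and sgRNA construction follows the assembly rules", {
  pre <- "TATATTAAACGCGAT" # verified: gains only the intended PAM in context
  d <- build_pair(pre, scaffold = "apFAB126")
  sc <- cs_scaffolds()$apFAB126
  expect_true(d$accepted)
  expect_equal(
    d$promoter_core,
    paste0(sc$minus35, pre, "GG", sc$minus10, sc$post)
  )
  # sgRNA operator = 6 nt of the -35 site + 14 5'-most nt of the pre
  expect_equal(nchar(d$sgrna_operator), 20L)
  expect_equal(d$sgrna_operator, paste0(sc$minus35, substr(pre, 1, 14)))
  # operator:PAM carries the completed NGG
  expect_equal(substr(d$operator_pam, 22, 23), "GG")
  expect_equal(nchar(d$handle), 82L)
  expect_error(build_pair(pre, scaffold = "nope"), "unknown scaffold")
  expect_error(build_pair("ACGT"), "15 nt")
})

test_that("designs gaining PAMs or BsaI sites are rejected", {
  # two extra NGG sites planted inside the operator region
  d_ngg <- build_pair("AGGAGGTATCGTATC")
  expect_false(d_ngg$accepted)
  expect_equal(d_ngg$reason, "extra_ngg")
  # an extra NAG (beyond the intended PAM) in context
  d_nag <- build_pair("ACTTACGATCGTAAC")
  # pre ending ...A places NAG right at the PAM junction
  d_nag2 <- build_pair("ACTTACGATCGTATA")
  expect_true(!d_nag$accepted || !d_nag2$accepted)
  # BsaI recognition site inside the insert
  d_bsai <- build_pair("TTTGAGACCTATTTC")
  expect_false(d_bsai$accepted)
  expect_equal(d_bsai$reason, "bsai_site")
})

test_that("accepted designs round-trip operator to promoter", {
  pres <- generate_presequences(300, seed = 9)
  for (pre in pres) {
    d <- build_pair(pre)
    if (!d$accepted) next
    # reverse-engineer the promoter operator from the sgRNA
    op14 <- substr(d$sgrna_operator, 7, 20)
    expect_equal(op14, substr(pre, 1, 14))
    expect_true(grepl(paste0(pre, "GG"), d$promoter_core, fixed = TRUE))
  }
})

test_that("off-target screening fires each rule on planted fixtures", {
  set.seed(14)
  genome <- random_dna(5000)
  pres <- generate_presequences(800, seed = 15)
  d <- NULL
  for (pre in pres) {
    cand <- build_pair(pre)
    if (cand$accepted &&
      offtarget_screen(cand, genome_target(genome)) == "pass") {
      d <- cand
      break
    }
  }
  expect_false(is.null(d))

  # plant the 12-nt 3' suffix of operator:PAM
  suf12 <- substr(d$operator_pam, 12, 23)
  g12 <- paste0(substr(genome, 1, 2000), suf12, substr(genome, 2013, 5000))
  expect_equal(offtarget_screen(d, genome_target(g12)), "fail_12nt_anywhere")

  # plant the 10-nt suffix inside an essential feature
  suf10 <- substr(d$operator_pam, 14, 23)
  g10 <- paste0(substr(genome, 1, 3000), suf10, substr(genome, 3011, 5000))
  ess <- data.frame(start = 3000, end = 3010)
  expect_equal(
    offtarget_screen(d, genome_target(g10, ess)), "fail_10nt_essential"
  )
  # without the essential overlap the 10-nt match alone is tolerated
  expect_equal(offtarget_screen(d, genome_target(g10)), "pass")

  # plant the 13-nt seed with one mismatch followed by a secondary PAM (TAG)
  seed13 <- substr(d$sgrna_operator, 8, 20)
  mismatched <- seed13
  substr(mismatched, 3, 3) <-
    setdiff(c("A", "C", "G", "T"), substr(seed13, 3, 3))[1]
  gsd <- paste0(
    substr(genome, 1, 1000), mismatched, "TAG", substr(genome, 1017, 5000)
  )
  expect_equal(
    offtarget_screen(d, genome_target(gsd)), "fail_seed_mismatch"
  )

  # the same planted site on the reverse strand is also caught
  rc_site <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste0(mismatched, "TAG"))
  ))
  grc <- paste0(
    substr(genome, 1, 1000), rc_site, substr(genome, 1017, 5000)
  )
  expect_equal(
    offtarget_screen(d, genome_target(grc)), "fail_seed_mismatch"
  )
})

test_that("off-target screen agrees with the sliding-window oracle", {
  set.seed(22)
  pres <- generate_presequences(1200, seed = 23)
  designs <- utils::head(
    Filter(function(d) d$accepted, lapply(pres, build_pair)), 3
  )
  expect_gte(length(designs), 1L)
  for (d in designs) {
    genome <- random_dna(4000)
    # plant assorted fragments of this design to exercise all rules
    frag12 <- substr(d$operator_pam, 12, 23)
    seed13 <- substr(d$sgrna_operator, 8, 20)
    mm <- seed13
    substr(mm, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(mm, 5, 5))[1]
    planted <- list(
      genome,
      paste0(substr(genome, 1, 500), frag12, substr(genome, 513, 4000)),
      paste0(substr(genome, 1, 900), mm, "CGG", substr(genome, 917, 4000)),
      paste0(
        substr(genome, 1, 700), substr(d$operator_pam, 14, 23),
        substr(genome, 711, 4000)
      )
    )
    ess <- data.frame(start = 650, end = 760)
    for (g in planted) {
      expect_equal(
        offtarget_screen(d, genome_target(g, ess)),
        oracle_offtarget(d, g, ess)
      )
    }
  }
})

test_that("match weights count co-occurring nucleotides", {
  a <- "ACTTACGATCGTATC"
  expect_equal(match_weight(a, a), 15L)
  b <- a
  substr(b, 4, 4) <- "G"
  expect_equal(match_weight(a, b), 14L)
  expect_error(match_weight(a, "ACGT"), "equal length")
  # brute-force position loop oracle on random pairs
  pres <- generate_presequences(40, seed = 31)
  set.seed(32)
  for (k in 1:200) {
    p <- sample(pres, 2)
    manual <- sum(vapply(
      1:15,
      function(i) substr(p[1], i, i) == substr(p[2], i, i), logical(1)
    ))
    expect_equal(match_weight(p[1], p[2]), manual)
  }
  g <- match_graph(pres)
  expect_equal(g$n_edges, 40 * 39 / 2)
  expect_true(all(g$weights == t(g$weights)))
  expect_true(all(diag(g$weights) == 0))
})

test_that("core-subset selection improves on chance and never backslides", {
  pres <- generate_presequences(12, seed = 7)
  cs <- select_core_subset(pres, core_size = 4, refinement_loops = 4)
  expect_lte(cs$total_weight, cs$initial_weight) # phase 2 never worsens
  W <- match_graph(pres)$weights
  combos <- utils::combn(12, 4)
  optimum <- min(apply(combos, 2, function(ix) sum(W[ix, ix]) / 2))
  expect_lte(cs$total_weight, 1.25 * optimum)

  # beats random subsets of the same size over 100 trials
  larger <- generate_presequences(60, seed = 8)
  sel <- select_core_subset(larger, core_size = 10)
  Wl <- match_graph(larger)$weights
  set.seed(9)
  random_tw <- replicate(100, {
    ix <- sample(60, 10)
    sum(Wl[ix, ix]) / 2
  })
  expect_lte(sel$total_weight, min(random_tw))
  expect_error(select_core_subset(pres, core_size = 100), "at least")

  # a weight-0 graph (four sequences disjoint at every position) is free
  zero <- c(
    paste(rep("A", 15), collapse = ""), paste(rep("C", 15), collapse = ""),
    paste(rep("G", 15), collapse = ""), paste(rep("T", 15), collapse = "")
  )
  z <- select_core_subset(zero, core_size = 2, refinement_loops = 1)
  expect_equal(z$total_weight, 0)
})

test_that("diverse-set expansion respects the cap and finds planted sets", {
  # no pair within the cap -> empty result
  same <- rep(paste(rep("A", 15), collapse = ""), 5)
  expect_equal(
    length(expand_diverse_sets(same, max_pair_weight = 5, min_size = 2,
      budget = 50, seed = 1)),
    0L
  )

  # constructed instance with exactly one valid 3-set: sequences 1-3 are
  # mutually dissimilar; 4-6 are near-copies of sequence 1
  base <- generate_presequences(3, seed = 41)
  near <- vapply(1:3, function(i) {
    s <- base[1]
    substr(s, i, i) <- c("A", "C", "G")[i]
    s
  }, character(1))
  inst <- c(base, unique(near))
  W <- match_graph(inst)$weights
  valid3 <- utils::combn(length(inst), 3)
  ok3 <- apply(valid3, 2, function(ix) all(W[ix, ix][upper.tri(W[ix, ix])] <= 5))
  found <- expand_diverse_sets(inst, max_pair_weight = 5, min_size = 3,
    budget = 300, seed = 2)
  if (sum(ok3) == 1) {
    expect_gte(length(found), 1L)
    target <- sort(inst[valid3[, which(ok3)]])
    expect_true(any(vapply(
      found, function(s) identical(sort(s), target), logical(1)
    )))
  }
  # every returned set satisfies the cap
  core <- generate_presequences(40, seed = 21)
  sets <- expand_diverse_sets(core, max_pair_weight = 5, min_size = 3,
    budget = 300, seed = 3)
  for (s in sets) {
    prs <- utils::combn(s, 2)
    w <- vapply(
      seq_len(ncol(prs)),
      function(i) match_weight(prs[1, i], prs[2, i]), integer(1)
    )
    expect_true(all(w <= 5))
  }
})

test_that("set scoring punishes 3'-end matches and breaks ties stably", {
  # two 2-member sets with equal match counts: one matches only at the 5'
  # end, the other only at the 3' end; ascending weights prefer the former
  s5a <- "AAAAACGTACGTACG"
  s5b <- "AAAAAGCATGCATGC" # matches at positions 1..5 only
  s3a <- "CGTACGTACGAAAAA"
  s3b <- "GCATGCATGCAAAAA" # matches at positions 11..15 only
  stopifnot(match_weight(s5a, s5b) == match_weight(s3a, s3b))
  pick <- score_and_pick(list(c(s3a, s3b), c(s5a, s5b)))
  expect_equal(sort(pick$set), sort(c(s5a, s5b)))

  single <- list(c(s5a, s5b))
  expect_equal(score_and_pick(single)$set, single[[1]])
  # exact tie -> lexicographically first serialized membership
  tie <- score_and_pick(list(c("B", "C"), c("A", "D")),
    position_weights = 1)
  expect_equal(sort(tie$set), c("A", "D"))
  expect_error(score_and_pick(list()), "no candidate")
  expect_error(
    score_and_pick(list(c(s5a, s5b)), position_weights = 15:1),
    "non-decreasing"
  )
})

test_that("insulators are motif-free on both strands and reproducible", {
  motifs <- default_forbidden_motifs()
  ins <- generate_insulator(seed = 5)
  expect_equal(nchar(ins), 70L)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(ins))
  )
  for (m in motifs) {
    expect_false(grepl(m, ins, fixed = TRUE))
    expect_false(grepl(m, rc, fixed = TRUE))
  }
  expect_identical(ins, generate_insulator(seed = 5))
  expect_error(
    generate_insulator(10, forbidden_motifs = c("A", "C", "G", "T"),
      seed = 1, max_attempts = 50),
    "attempts"
  )
})

test_that("promoter insulation yields exactly 105 bp", {
  ins <- generate_insulator(seed = 5)
  core35 <- build_pair("TATATTAAACGCGAT")$promoter_core
  out <- insulate_promoter(core35, ins)
  expect_equal(nchar(out), 105L)
  expect_true(endsWith(out, core35))
  expect_equal(substr(out, 1, 70), ins) # 35 + 70 = 105: untruncated

  core40 <- paste0(core35, "ACGTA") # 40 bp
  out40 <- insulate_promoter(core40, ins)
  expect_equal(nchar(out40), 105L)
  expect_equal(substr(out40, 1, 65), substr(ins, 6, 70)) # 5' truncated

  core105 <- strrep("A", 105)
  expect_equal(insulate_promoter(core105, ins), core105)
  expect_error(insulate_promoter(strrep("A", 106), ins), "longer")
})

test_that("the full design pipeline yields a pairwise-diverse library", {
  set.seed(51)
  genome <- random_dna(20000)
  lib <- design_guide_library(
    genome_target(genome),
    n = 2500, core_size = 15, refinement_loops = 2,
    max_pair_weight = 5, min_size = 4, budget = 400, seed = 61
  )
  expect_gte(nrow(lib$library), 4L)
  expect_true(all(nchar(lib$library$insulated_promoter) == 105L))
  prs <- utils::combn(lib$library$pre, 2)
  w <- vapply(
    seq_len(ncol(prs)),
    function(i) match_weight(prs[1, i], prs[2, i]), integer(1)
  )
  expect_true(all(w <= 5))
  expect_true(all(c("construction", "offtarget") %in% names(lib$verdicts)))
})
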