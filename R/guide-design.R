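# Orthogonal sgRNA:promoter library design: pre-sequence generation,
# promoter/sgRNA construction with PAM and restriction-site filters, genomic
# off-target screening, graph-based diverse-subset selection, and promoter
# insulation.

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Generate random pre-sequences
#'
#' A pre-sequence is the 15-nt randomized core of one sgRNA:promoter pair:
#' the 3'-most 14 nucleotides of the CRISPRi operator (including the
#' specificity-conveying seed) followed by 1 nucleotide encoding the first,
#' degenerate position of the adjacent NGG PAM. Bases are drawn
#' independently with a ~40% GC bias (G and C at probability 0.2 each,
#' A and T at 0.3 each).
#'
#' @param n Number of pre-sequences.
#' @param seed Optional integer seed; the same seed reproduces the same list.
#' @return Character vector of 15-nt sequences.
#' @export
generate_presequences <- function(n, seed = NULL) {
  stopifnot(n >= 1)
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    probs <- c(0.3, 0.2, 0.2, 0.3)
    vapply(seq_len(n), function(i) {
      paste(sample(bases, 15, replace = TRUE, prob = probs), collapse = "")
    }, character(1))
  })
}

#' Promoter scaffolds for sgRNA:promoter construction
#'
#' Each scaffold contributes the -35 and -10 hexamers (and a short
#' downstream context to the transcription start) between which a
#' pre-sequence:GG operator is inserted. The shipped table uses the
#' sigma70-consensus-like hexamers for the strong synthetic scaffold
#' (`apFAB126`) and the TTGACT/GATAAT hexamers of the lambda P_R scaffold
#' (`PR`); all fields can be overridden by passing a modified table to
#' [build_pair()].
#'
#' @return A named list of scaffolds, each with `minus35`, `minus10` and
#'   `post` (6 nt downstream of -10) character fields.
#' @export
cs_scaffolds <- function() {
  list(
    apFAB126 = list(minus35 = "TTGACA", minus10 = "TATAAT", post = "ATACAT"),
    PR = list(minus35 = "TTGACT", minus10 = "GATAAT", post = "ATTCAT")
  )
}

#' The constant sgRNA handle used downstream of the operator
#'
#' 82 nt: the canonical 76-nt S. pyogenes Cas9 sgRNA scaffold followed by a
#' 6-nt poly-T terminator. Replaceable by any 82-nt constant.
#'
#' @return A character scalar of length-82 sequence.
#' @export
sgrna_handle <- function() {
  paste0(
    "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAACTTGAAAAAGTGGCACCGAGTCGGTGC",
    "TTTTTT"
  )
}

# Count overlapping NGG / NAG PAM occurrences on both strands of a sequence.
# An NGG needs one base of context 5' of the GG, so "GG" must start at
# position >= 2.
count_pams <- function(seq) {
  count_motif <- function(s, core) {
    n <- nchar(s)
    if (n < 3) {
      return(0L)
    }
    starts <- 2:(n - 1)
    sum(substring(s, starts, starts + 1) == core)
  }
  rc <- revcomp(seq)
  c(
    ngg = count_motif(seq, "GG") + count_motif(rc, "GG"),
    nag = count_motif(seq, "AG") + count_motif(rc, "AG")
  )
}

#' Build one sgRNA:promoter pair from a pre-sequence
#'
#' Constructs the promoter by inserting `pre`:GG between the scaffold's -35
#' and -10 hexamers (the appended GG completes the NGG PAM), and the sgRNA
#' operator as the 6 nt of the -35 site plus the 5'-most 14 nt of the
#' pre-sequence (20 nt total), followed by the 82-nt constant handle. The
#' design is rejected when the promoter gains more than one additional NGG
#' or any additional NAG PAM relative to the bare scaffold (both strands
#' counted), or contains a BsaI recognition site (GGTCTC / GAGACC), which
#' would interfere with Golden Gate assembly.
#'
#' @param pre A 15-nt pre-sequence (ACGT).
#' @param scaffold `"apFAB126"` or `"PR"` (a name in `scaffolds`).
#' @param scaffolds Scaffold table, see [cs_scaffolds()].
#' @return A `guide_design` list: `pre`, `scaffold`, `promoter_core`,
#'   `sgrna_operator`, `operator_pam` (operator plus 3-nt PAM), `handle`,
#'   `accepted` and `reason` (`NA` when accepted).
#' @export
build_pair <- function(pre, scaffold = "apFAB126", scaffolds = cs_scaffolds()) {
  if (nchar(pre) != 15 || grepl("[^ACGT]", pre)) {
    stop("pre-sequence must be 15 nt over ACGT", call. = FALSE)
  }
  if (!scaffold %in% names(scaffolds)) {
    stop("unknown scaffold: ", scaffold, call. = FALSE)
  }
  sc <- scaffolds[[scaffold]]
  promoter <- paste0(sc$minus35, pre, "GG", sc$minus10, sc$post)
  baseline <- paste0(sc$minus35, sc$minus10, sc$post)
  operator <- paste0(sc$minus35, substr(pre, 1, 14))
  operator_pam <- paste0(operator, substr(pre, 15, 15), "GG")

  added <- count_pams(promoter) - count_pams(baseline)
  reason <- NA_character_
  # BsaI is reported first: a Golden Gate incompatibility is absolute, and
  # its GGTCTC/GAGACC site also registers as a strand-reversed PAM gain
  if (grepl("GGTCTC", promoter, fixed = TRUE) ||
    grepl("GAGACC", promoter, fixed = TRUE)) {
    reason <- "bsai_site"
  } else if (added[["ngg"]] > 1L) {
    reason <- "extra_ngg"
  } else if (added[["nag"]] > 0L) {
    reason <- "extra_nag"
  }
  structure(
    list(
      pre = pre, scaffold = scaffold, promoter_core = promoter,
      sgrna_operator = operator, operator_pam = operator_pam,
      handle = sgrna_handle(),
      accepted = is.na(reason), reason = reason
    ),
    class = "guide_design"
  )
}

#' @export
print.guide_design <- function(x, ...) {
  cat(
    "<guide_design>", x$scaffold,
    if (x$accepted) "accepted" else paste0("rejected (", x$reason, ")"), "\n",
    " promoter:", x$promoter_core, "\n",
    " operator:", x$sgrna_operator, "PAM:",
    substr(x$operator_pam, 21, 23), "\n"
  )
  invisible(x)
}

#' Genome plus essential-feature annotation for off-target screening
#'
#' @param genome A DNA sequence: character scalar, `Biostrings::DNAString`,
#'   or path to a FASTA file (first record used).
#' @param essential Essential features: a data frame with 0-based half-open
#'   `start`/`end` columns, or a path to a GFF3/BED file (imported via
#'   rtracklayer when installed; coordinates converted to 0-based
#'   half-open). `NULL` for none.
#' @return A `genome_target` list with `genome` (DNAString) and
#'   `essential` (tibble with `start`, `end`).
#' @export
genome_target <- function(genome, essential = NULL) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)[[1]]
  } else if (is.character(genome)) {
    genome <- Biostrings::DNAString(genome)
  }
  stopifnot(inherits(genome, "DNAString"))
  if (is.character(essential)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GFF/BED needs the rtracklayer package", call. = FALSE)
    }
    gr <- rtracklayer::import(essential)
    essential <- tibble::tibble(
      start = BiocGenerics::start(gr) - 1L, end = BiocGenerics::end(gr)
    )
  }
  if (is.null(essential)) {
    essential <- tibble::tibble(start = integer(0), end = integer(0))
  }
  essential <- tibble::as_tibble(essential)[, c("start", "end")]
  if (nrow(essential) &&
    (any(essential$start < 0) || any(essential$end > length(genome)))) {
    stop("essential features must lie within the genome", call. = FALSE)
  }
  structure(
    list(genome = genome, essential = essential),
    class = "genome_target"
  )
}

# All 0-based half-open footprints of `pattern` in the target genome, both
# strands, reported in forward coordinates; optionally with mismatches, and
# with the matched strand and (for seed scans) the strand-local start kept.
scan_genome <- function(g, pattern, max.mismatch = 0) {
  L <- length(g$genome)
  w <- nchar(pattern)
  hits_fwd <- Biostrings::matchPattern(
    pattern, g$genome,
    max.mismatch = max.mismatch
  )
  rc <- Biostrings::reverseComplement(g$genome)
  hits_rev <- Biostrings::matchPattern(pattern, rc,
    max.mismatch = max.mismatch
  )
  fwd <- tibble::tibble(
    start = BiocGenerics::start(hits_fwd) - 1L,
    strand = "+",
    local_start = BiocGenerics::start(hits_fwd) - 1L
  )
  rev <- tibble::tibble(
    start = L - (BiocGenerics::start(hits_rev) - 1L) - w,
    strand = "-",
    local_start = BiocGenerics::start(hits_rev) - 1L
  )
  out <- dplyr::bind_rows(fwd, rev)
  out$end <- out$start + w
  out
}

overlaps_essential <- function(hits, essential) {
  if (!nrow(hits) || !nrow(essential)) {
    return(FALSE)
  }
  for (i in seq_len(nrow(hits))) {
    if (any(hits$start[i] < essential$end & essential$start < hits$end[i])) {
      return(TRUE)
    }
  }
  FALSE
}

# Extend a 3'-suffix hit leftward while the genome keeps matching the
# operator:PAM, and return the full matched footprint (forward coords).
extend_suffix_hits <- function(g, hits, operator_pam, base_w) {
  if (!nrow(hits)) {
    return(hits)
  }
  seq_fwd <- as.character(g$genome)
  seq_rev <- revcomp(seq_fwd)
  L <- nchar(seq_fwd)
  n_op <- nchar(operator_pam)
  for (i in seq_len(nrow(hits))) {
    s <- if (hits$strand[i] == "+") seq_fwd else seq_rev
    p <- hits$local_start[i] # 0-based start of the base_w-mer on its strand
    ext <- 0L
    while (base_w + ext < n_op && p - ext - 1L >= 0L &&
      substr(s, p - ext, p - ext) ==
        substr(operator_pam, n_op - base_w - ext, n_op - base_w - ext)) {
      ext <- ext + 1L
    }
    if (hits$strand[i] == "+") {
      hits$start[i] <- hits$start[i] - ext
    } else {
      hits$end[i] <- hits$end[i] + ext
    }
  }
  hits
}

#' Off-target screen of a guide design against a genome
#'
#' Applies, in order, the three screening rules used for the library design,
#' reporting the first that fails:
#' \enumerate{
#'   \item any genomic match of the 3'-most 10 or more nucleotides of the
#'     operator:PAM sequence whose footprint overlaps an essential feature
#'     (`fail_10nt_essential`);
#'   \item any genomic match of the 3'-most 12 or more nucleotides of the
#'     operator:PAM, anywhere (`fail_12nt_anywhere`);
#'   \item any genomic site matching the 13-nt seed (the 3'-most 13
#'     nucleotides of the operator) exactly or with one mismatch and
#'     adjacent to a primary (NGG) or secondary (NAG) PAM
#'     (`fail_seed_mismatch`).
#' }
#' Both strands are scanned; coordinates are 0-based half-open.
#'
#' @param design A [build_pair()] result.
#' @param target A [genome_target()].
#' @return One of `"pass"`, `"fail_10nt_essential"`, `"fail_12nt_anywhere"`,
#'   `"fail_seed_mismatch"`.
#' @export
offtarget_screen <- function(design, target) {
  stopifnot(inherits(design, "guide_design"), inherits(target, "genome_target"))
  op <- design$operator_pam # 23 nt: 20-nt operator + 3-nt PAM
  n_op <- nchar(op)

  suffix10 <- substr(op, n_op - 9, n_op)
  hits10 <- extend_suffix_hits(target, scan_genome(target, suffix10), op, 10L)
  if (overlaps_essential(hits10, target$essential)) {
    return("fail_10nt_essential")
  }

  suffix12 <- substr(op, n_op - 11, n_op)
  if (nrow(scan_genome(target, suffix12)) > 0) {
    return("fail_12nt_anywhere")
  }

  operator <- design$sgrna_operator
  seed <- substr(operator, nchar(operator) - 12, nchar(operator))
  seed_hits <- scan_genome(target, seed, max.mismatch = 1)
  if (nrow(seed_hits)) {
    seq_fwd <- as.character(target$genome)
    seq_rev <- revcomp(seq_fwd)
    for (i in seq_len(nrow(seed_hits))) {
      s <- if (seed_hits$strand[i] == "+") seq_fwd else seq_rev
      p <- seed_hits$local_start[i] # 0-based
      pam <- substr(s, p + 15, p + 16) # the 2 nt after the degenerate N
      if (p + 16 <= nchar(s) && pam %in% c("GG", "AG")) {
        return("fail_seed_mismatch")
      }
    }
  }
  "pass"
}

#' Pairwise match weight between two pre-sequences
#'
#' The number of positions (of 15 possible) at which two pre-sequences carry
#' the same nucleotide — the edge weight of the match graph.
#'
#' @param a,b Pre-sequences of equal length.
#' @return Integer count of co-occurring nucleotides.
#' @export
match_weight <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("pre-sequences must have equal length", call. = FALSE)
  }
  sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
}

#' Complete match graph over a set of pre-sequences
#'
#' Vertices are pre-sequences; every pair is joined by an edge weighted by
#' its [match_weight()]. The graph is stored as the symmetric weight matrix.
#'
#' @param pres Character vector of equal-length pre-sequences.
#' @return A `match_graph` list: `pres`, `weights` (integer matrix with zero
#'   diagonal), `n_vertices`, `n_edges` (`choose(n, 2)`).
#' @export
match_graph <- function(pres) {
  n <- length(pres)
  k <- nchar(pres[1])
  stopifnot(all(nchar(pres) == k))
  chars <- matrix(unlist(strsplit(pres, "")), nrow = n, byrow = TRUE)
  W <- matrix(0L, n, n)
  for (j in seq_len(k)) {
    W <- W + outer(chars[, j], chars[, j], "==")
  }
  diag(W) <- 0L
  storage.mode(W) <- "integer"
  structure(
    list(
      pres = pres, weights = W, n_vertices = n,
      n_edges = n * (n - 1) / 2
    ),
    class = "match_graph"
  )
}

#' @export
print.match_graph <- function(x, ...) {
  cat(
    "<match_graph>", x$n_vertices, "pre-sequences,",
    format(x$n_edges, big.mark = ","), "edges\n"
  )
  invisible(x)
}

total_pairwise_weight <- function(W, idx) {
  if (length(idx) < 2) {
    return(0L)
  }
  sum(W[idx, idx]) / 2
}

#' Select a low-similarity core subset of pre-sequences
#'
#' Two-phase heuristic minimizing the total pairwise match weight of a
#' `core_size`-vertex subgraph. Phase 1 sorts all edges by ascending weight
#' (ties by edge enumeration order) and collects their endpoints until
#' `core_size` vertices are selected. Phase 2 makes `refinement_loops`
#' passes over the excluded pre-sequences: each is added to the subset and
#' the member contributing the most matches to the enlarged subset is
#' discarded, so the total weight never increases.
#'
#' @param pres Character vector of pre-sequences (length >= `core_size`).
#' @param core_size Target subset size.
#' @param refinement_loops Number of phase-2 passes.
#' @param graph Optional precomputed [match_graph()] of `pres`.
#' @return A list with `subset` (pre-sequences), `indices`, `total_weight`
#'   and `initial_weight` (after phase 1).
#' @export
select_core_subset <- function(pres, core_size = 100, refinement_loops = 4,
                               graph = NULL) {
  n <- length(pres)
  if (n < core_size) {
    stop("need at least core_size pre-sequences", call. = FALSE)
  }
  if (is.null(graph)) graph <- match_graph(pres)
  W <- graph$weights

  # phase 1: collect vertices from ascending-weight edges
  pair_i <- rep(seq_len(n - 1), times = (n - 1):1)
  pair_j <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  ew <- W[cbind(pair_i, pair_j)]
  ord <- order(ew) # stable: ties stay in (i, j) enumeration order
  sel <- logical(n)
  count <- 0L
  for (e in ord) {
    for (v in c(pair_i[e], pair_j[e])) {
      if (!sel[v] && count < core_size) {
        sel[v] <- TRUE
        count <- count + 1L
      }
    }
    if (count >= core_size) break
  }
  idx <- which(sel)
  initial_weight <- total_pairwise_weight(W, idx)

  # phase 2: swap-in each excluded sequence, discard the worst contributor
  for (loop in seq_len(refinement_loops)) {
    excluded <- setdiff(seq_len(n), idx)
    for (e in excluded) {
      cand <- c(idx, e)
      contrib <- colSums(W[cand, cand, drop = FALSE])
      worst <- cand[which.max(contrib)] # ties: first (lowest position)
      idx <- setdiff(cand, worst)
    }
  }
  list(
    subset = pres[idx], indices = idx,
    total_weight = total_pairwise_weight(W, idx),
    initial_weight = initial_weight
  )
}

#' Expand low-similarity seed pairs into maximal diverse sets
#'
#' Seeds are all pairs of pre-sequences with match weight at most
#' `max_pair_weight`. Each expansion picks a random seed and grows it one
#' random compatible member at a time (compatible: pairwise weight to every
#' current member stays within the cap) until maximal; maximal sets of at
#' least `min_size` members are collected, de-duplicated, across `budget`
#' expansions.
#'
#' @param core Character vector of pre-sequences (e.g. a core subset).
#' @param max_pair_weight Pairwise match-weight cap (default 5).
#' @param min_size Minimum set size to retain (default 10).
#' @param budget Number of seed expansions.
#' @param seed Optional RNG seed.
#' @return A list of character vectors (possibly empty), each a maximal set
#'   with all pairwise weights within the cap.
#' @export
expand_diverse_sets <- function(core, max_pair_weight = 5, min_size = 10,
                                budget = 10000, seed = NULL) {
  n <- length(core)
  if (n < 2) {
    return(list())
  }
  W <- match_graph(core)$weights
  ok <- W <= max_pair_weight
  pairs <- which(upper.tri(W) & ok, arr.ind = TRUE)
  if (!nrow(pairs)) {
    return(list())
  }
  with_seed(seed, {
    found <- new.env(parent = emptyenv())
    for (b in seq_len(budget)) {
      p <- pairs[sample.int(nrow(pairs), 1), ]
      members <- c(p[[1]], p[[2]])
      compat <- which(ok[, members[1]] & ok[, members[2]])
      compat <- setdiff(compat, members)
      while (length(compat)) {
        add <- compat[sample.int(length(compat), 1)]
        members <- c(members, add)
        compat <- setdiff(compat[ok[compat, add]], add)
      }
      if (length(members) >= min_size) {
        key <- paste(sort(members), collapse = ",")
        found[[key]] <- sort(members)
      }
    }
    keys <- sort(ls(found))
    lapply(keys, function(k) core[found[[k]]])
  })
}

#' Score candidate sets and pick the most 3'-divergent one
#'
#' Each edge of a candidate set is scored as the sum of `position_weights`
#' over its matching positions; ascending weights toward the 3' end punish
#' seed-proximal matches, which dominate CRISPRi specificity. The set with
#' the lowest mean edge score wins; ties break lexicographically on the
#' serialized (sorted) membership.
#'
#' @param sets A non-empty list of character vectors of pre-sequences.
#' @param position_weights 15 positive, non-decreasing weights (default
#'   `1:15`, ascending toward the 3' end).
#' @return A list with `set` (the chosen members), `score` and a `scores`
#'   tibble over all candidates.
#' @export
score_and_pick <- function(sets, position_weights = 1:15) {
  if (!length(sets)) stop("no candidate sets to score", call. = FALSE)
  if (any(position_weights <= 0) || is.unsorted(position_weights)) {
    stop("position weights must be positive and non-decreasing", call. = FALSE)
  }
  edge_score <- function(a, b) {
    sum(position_weights[strsplit(a, "")[[1]] == strsplit(b, "")[[1]]])
  }
  set_score <- function(s) {
    if (length(s) < 2) {
      return(0)
    }
    prs <- utils::combn(s, 2)
    mean(vapply(
      seq_len(ncol(prs)),
      function(i) edge_score(prs[1, i], prs[2, i]), numeric(1)
    ))
  }
  scores <- vapply(sets, set_score, numeric(1))
  keys <- vapply(sets, function(s) paste(sort(s), collapse = ","), character(1))
  best <- order(scores, keys)[1]
  list(
    set = sets[[best]], score = scores[best],
    scores = tibble::tibble(set = keys, score = scores)
  )
}

#' Default forbidden-motif catalog for insulator screening
#'
#' Motifs excluded from randomly generated insulators: sigma70 -35/-10
#' consensus hexamers, a strong Shine-Dalgarno core, BsaI and common cloning
#' enzyme recognition sites, and homopolymer runs. The catalog is a
#' configurable starting point, not an exhaustive regulatory-site database.
#'
#' @return Character vector of motifs.
#' @export
default_forbidden_motifs <- function() {
  c(
    "TTGACA", "TATAAT", # sigma70 consensus -35 / -10
    "AGGAGG", # strong RBS (Shine-Dalgarno core)
    "GGTCTC", "GAGACC", # BsaI
    "GAATTC", "GGATCC", "AAGCTT", "TCTAGA", "ACTAGT", # common RE sites
    "AAAAAAAA", "TTTTTTTT", "GGGGGGGG", "CCCCCCCC" # unwieldy repeats
  )
}

#' Generate an insulator sequence free of forbidden motifs
#'
#' Rejection-samples uniform random DNA until no forbidden motif occurs on
#' either strand.
#'
#' @param length Insulator length, nt (default 70).
#' @param forbidden_motifs Motif catalog; see [default_forbidden_motifs()].
#' @param seed Optional RNG seed (same seed and motif list reproduce the
#'   same sequence).
#' @param max_attempts Bound on rejection sampling before failing.
#' @return A character scalar of the requested length.
#' @export
generate_insulator <- function(length = 70,
                               forbidden_motifs = default_forbidden_motifs(),
                               seed = NULL, max_attempts = 10000) {
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      s <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
        collapse = ""
      )
      rc <- revcomp(s)
      hit <- any(vapply(forbidden_motifs, function(m) {
        grepl(m, s, fixed = TRUE) || grepl(m, rc, fixed = TRUE)
      }, logical(1)))
      if (!hit) {
        return(s)
      }
    }
    stop("no motif-free insulator found within ", max_attempts, " attempts",
      call. = FALSE
    )
  })
}

#' Insulate a core promoter to a standard total length
#'
#' Prepends the insulator to the promoter core, truncating the insulator
#' from its 5' end so the total length is exactly 105 bp.
#'
#' @param core Core promoter sequence (at most 105 bp).
#' @param insulator Insulator sequence, see [generate_insulator()].
#' @param total_length Target length (default 105 bp).
#' @return The insulated promoter sequence.
#' @export
insulate_promoter <- function(core, insulator, total_length = 105) {
  nc <- nchar(core)
  if (nc > total_length) {
    stop("core promoter longer than the target total length", call. = FALSE)
  }
  needed <- total_length - nc
  ni <- nchar(insulator)
  if (needed > ni) {
    stop("insulator too short to reach the target total length",
      call. = FALSE
    )
  }
  paste0(substr(insulator, ni - needed + 1, ni), core)
}

#' Run the full library-design pipeline
#'
#' Pre-sequences are generated, built into promoter/sgRNA pairs (PAM and
#' BsaI filters), screened against the genome for off-targets, reduced to a
#' low-similarity core subset, expanded into diverse candidate sets, scored
#' with 3'-weighted position weights, and the winning set's promoters are
#' insulated to 105 bp.
#'
#' @param target A [genome_target()] for off-target screening.
#' @param n Number of pre-sequences to draw.
#' @param scaffold Scaffold name for construction.
#' @param core_size,refinement_loops Core-subset parameters.
#' @param max_pair_weight,min_size,budget Diverse-set expansion parameters.
#' @param position_weights Scoring weights, ascending toward 3'.
#' @param seed RNG seed driving every random step.
#' @return A list with `library` (tibble: `pre`, `promoter_core`,
#'   `sgrna_operator`, `insulated_promoter`), `verdicts` (per-candidate
#'   screen outcomes), `core` and `n_candidate_sets`.
#' @export
design_guide_library <- function(target, n = 3000, scaffold = "apFAB126",
                                 core_size = 100, refinement_loops = 4,
                                 max_pair_weight = 5, min_size = 10,
                                 budget = 10000, position_weights = 1:15,
                                 seed = 1) {
  pres <- generate_presequences(n, seed = seed)
  designs <- lapply(pres, build_pair, scaffold = scaffold)
  verdicts <- tibble::tibble(
    pre = pres,
    construction = vapply(designs, function(d) {
      if (d$accepted) "accepted" else d$reason
    }, character(1)),
    offtarget = NA_character_
  )
  keep <- which(verdicts$construction == "accepted")
  verdicts$offtarget[keep] <- vapply(
    designs[keep], offtarget_screen, character(1),
    target = target
  )
  passed <- which(!is.na(verdicts$offtarget) & verdicts$offtarget == "pass")
  if (length(passed) < max(core_size, min_size)) {
    stop("too few pre-sequences survive screening; increase n", call. = FALSE)
  }
  core <- select_core_subset(pres[passed],
    core_size = min(core_size, length(passed)),
    refinement_loops = refinement_loops
  )
  sets <- expand_diverse_sets(core$subset,
    max_pair_weight = max_pair_weight,
    min_size = min_size, budget = budget, seed = seed + 1L
  )
  if (!length(sets)) {
    stop("no diverse sets of the requested size found; lower min_size",
      call. = FALSE
    )
  }
  chosen <- score_and_pick(sets, position_weights)
  insulator <- generate_insulator(seed = seed + 2L)
  lib <- tibble::tibble(pre = chosen$set)
  built <- lapply(lib$pre, build_pair, scaffold = scaffold)
  lib$promoter_core <- vapply(built, `[[`, character(1), "promoter_core")
  lib$sgrna_operator <- vapply(built, `[[`, character(1), "sgrna_operator")
  lib$insulated_promoter <- vapply(
    lib$promoter_core, insulate_promoter, character(1),
    insulator = insulator,
    USE.NAMES = FALSE
  )
  list(
    library = lib, verdicts = verdicts, core = core,
    n_candidate_sets = length(sets)
  )
}
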