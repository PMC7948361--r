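# pas_discovery: trimming, dedup, A-stretches, artifact filter,
# clustering, windows, quantification.

test_that("trim_polya matches the pinned sliding-window semantics", {
  a <- trim_polya(paste0("ACGTACGT", strrep("A", 10)))
  expect_identical(a$trimmed, "ACGTACGT")
  expect_equal(a$n_trailing_a, 10L)
  expect_true(a$is_polya)

  b <- trim_polya(paste0("ACGTACGT", strrep("A", 9)))
  expect_identical(b$trimmed, paste0("ACGTACGT", strrep("A", 9)))
  expect_false(b$is_polya)

  c <- trim_polya("ACGTAAAAAGAAAAAA")
  expect_identical(c$trimmed, "ACGT")
  expect_equal(c$n_trailing_a, 11L)
  expect_true(c$is_polya)
})

test_that("reads shorter than 5 nt after trimming are unusable", {
  r <- trim_polya(paste0("ACG", strrep("A", 12)))
  expect_false(r$usable)
  expect_true(trim_polya(paste0("ACGTC", strrep("A", 12)))$usable)
})

test_that("prepare_reads dedups on UMI + coordinate and logs counts", {
  reads <- data.frame(
    read_id = c("r1", "r2", "r3", "r4"),
    umi = c("AAAAAAAA", "AAAAAAAA", "AAAAAAAA", NA),
    seq = rep(paste0("ACGTACGTCC", strrep("A", 12)), 4),
    stringsAsFactors = FALSE)
  positions <- data.frame(read_id = c("r1", "r2", "r3", "r4"),
                          contig = "chr1", strand = "+",
                          position = c(100L, 100L, 250L, 300L),
                          stringsAsFactors = FALSE)
  expect_warning(prep <- prepare_reads(reads, positions), "UMI")
  expect_equal(nrow(prep$reads), 2L)        # 100 kept once, 250 kept
  expect_equal(prep$log$n_duplicates_removed, 1L)
  expect_equal(prep$log$n_missing_umi, 1L)
})

test_that("quality trimming removes low-Phred terminal bases", {
  seq <- paste0("GG", "ACGTACGTCC", strrep("A", 12))
  qual <- paste0("++", strrep("I", 10 + 12))   # '+' = Phred 10 < 16
  reads <- data.frame(read_id = "r1", umi = "ACGTACGT",
                      seq = seq, qual = qual, stringsAsFactors = FALSE)
  prep <- prepare_reads(reads)
  expect_identical(prep$reads$trimmed, "ACGTACGTCC")
})

test_that("prepare_reads is idempotent", {
  sim <- simulate_genome(n_genes = 3, seed = 21L)
  mace <- simulate_mace_reads(sim, reads_per_pas = 8,
                              duplicate_rate = 0.3, seed = 21L)
  pos <- data.frame(read_id = mace$reads$read_id,
                    contig = mace$reads$contig,
                    strand = mace$reads$strand,
                    position = mace$reads$read3p,
                    stringsAsFactors = FALSE)
  once <- prepare_reads(mace$reads, pos)
  again <- prepare_reads(
    transform(once$reads, seq = trimmed), pos)
  expect_identical(again$reads$read_id, once$reads$read_id)
  expect_equal(again$log$n_duplicates_removed, 0L)
})

test_that("A-stretch discovery matches window enumeration oracles", {
  g <- toy_genome(chr1 = paste0(strrep("CG", 20), strrep("A", 12),
                                strrep("CG", 20)))
  st <- find_genomic_a_stretches(g)
  plus <- st[st$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(c(plus$start, plus$end), c(41L, 52L))

  # 5A,2C,5A merges into one stretch (2 errors per window allowed)
  g2 <- toy_genome(chr1 = paste0(strrep("CG", 20), "AAAAACCAAAAA",
                                 strrep("CG", 20)))
  st2 <- find_genomic_a_stretches(g2)
  expect_equal(nrow(st2[st2$strand == "+", ]), 1L)

  # T-stretch appears on the minus strand only
  g3 <- toy_genome(chr1 = paste0(strrep("CG", 20), strrep("T", 12),
                                 strrep("CG", 20)))
  st3 <- find_genomic_a_stretches(g3)
  expect_identical(unique(st3$strand), "-")
})

test_that("internal-priming filter applies the adjacency rule", {
  stretches <- data.frame(contig = "chr1", strand = "+",
                          start = c(103L, 120L), end = c(114L, 131L),
                          stringsAsFactors = FALSE)
  ev <- data.frame(contig = "chr1", strand = "+",
                   position = c(100L, 100L), sample_id = c("s", "s2"),
                   count = 1L, stringsAsFactors = FALSE)
  res <- filter_internal_priming(ev, stretches[1, ], adjacency_nt = 5L)
  expect_equal(res$n_removed, 2L)           # start 103 within 5 nt
  res2 <- filter_internal_priming(ev, stretches[2, ], adjacency_nt = 5L)
  expect_equal(res2$n_removed, 0L)          # start 120 outside

  # minus strand mirror: stretch tx-start is its genomic end
  ev_m <- data.frame(contig = "chr1", strand = "-", position = 200L,
                     sample_id = "s", count = 1L,
                     stringsAsFactors = FALSE)
  st_m <- data.frame(contig = "chr1", strand = "-", start = 185L,
                     end = 197L, stringsAsFactors = FALSE)
  expect_equal(filter_internal_priming(ev_m, st_m)$n_removed, 1L)
})

test_that("cleavage events sit 1 nt downstream of the trimmed 3' end", {
  prepared <- list(reads = data.frame(
    contig = "chr1", strand = c("+", "-"), position = c(100L, 100L),
    is_polya = TRUE, sample_id = "s1", stringsAsFactors = FALSE))
  ev <- cleavage_events_from_reads(prepared)
  expect_setequal(ev$position, c(101L, 99L))
})

test_that("clustering reproduces the worked examples", {
  ev <- data.frame(contig = "chr1", strand = "+",
                   position = c(100L, 101L, 103L, 150L),
                   count = c(1L, 2L, 1L, 1L), stringsAsFactors = FALSE)
  cl <- cluster_cleavage_events(ev)
  ids <- cl$cluster_id[match(c(100, 101, 103, 150), cl$position)]
  expect_equal(length(unique(ids[1:3])), 1L)
  expect_false(ids[4] == ids[1])

  # minus-strand processed in descending order -> one cluster
  ev_m <- data.frame(contig = "chr1", strand = "-",
                     position = c(500L, 480L, 479L), count = 1L,
                     stringsAsFactors = FALSE)
  expect_equal(length(unique(cluster_cleavage_events(ev_m)$cluster_id)),
               1L)

  # singleton
  ev_s <- data.frame(contig = "chr1", strand = "+", position = 50L,
                     count = 1L, stringsAsFactors = FALSE)
  expect_equal(nrow(cluster_cleavage_events(ev_s)), 1L)
})

test_that("clustering matches the independent oracle on 1,000 fuzz cases", {
  set.seed(42)
  for (case in 1:1000) {
    n <- sample(1:20, 1)
    strand <- sample(c("+", "-"), 1)
    pos <- sort(sample(1:300, n))
    cnt <- sample(1:4, n, replace = TRUE)
    ev <- data.frame(contig = "chr1", strand = strand, position = pos,
                     count = cnt, stringsAsFactors = FALSE)
    got <- cluster_cleavage_events(ev, max_dist = 25L)
    got <- got[pasatlas:::tx_order(got$position, strand), ]
    want <- oracle_cluster(pos, cnt, strand, 25)
    expect_identical(as.integer(factor(got$cluster_id,
                                       levels = unique(got$cluster_id))),
                     want)
  }
})

test_that("windows take the mode center with upstream tie-break", {
  cl <- data.frame(contig = "chr1", strand = "+",
                   position = c(100L, 101L, 103L), count = c(3L, 1L, 2L),
                   cluster_id = "cl00001", stringsAsFactors = FALSE)
  w <- define_pas_windows(cl)
  expect_equal(w$center, 100L)
  expect_equal(c(w$start, w$end), c(93L, 107L))
  expect_equal(w$end - w$start + 1L, 15L)

  tie <- data.frame(contig = "chr1", strand = "+",
                    position = c(100L, 104L), count = c(2L, 2L),
                    cluster_id = "cl00001", stringsAsFactors = FALSE)
  expect_equal(define_pas_windows(tie)$center, 100L)
  tie$strand <- "-"
  expect_equal(define_pas_windows(tie)$center, 104L)
})

test_that("quantification implements the CE/PU/TPM formulas and filter", {
  models <- toy_models()
  windows <- data.frame(window_id = c("w1", "w2"), contig = "chr1",
                        strand = "+", center = c(450L, 550L),
                        start = c(443L, 543L), end = c(457L, 557L),
                        n_events = 0L, gene_id = "gA",
                        stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = c("s1", "s2"),
                        condition = c("ctrl", "kd"),
                        stringsAsFactors = FALSE)
  ev <- data.frame(contig = "chr1", strand = "+",
                   position = c(rep(450L, 10), rep(550L, 30)),
                   sample_id = "s1", count = 1L,
                   stringsAsFactors = FALSE)
  ev <- pool_events(ev)
  ev$sample_id <- "s1"
  q <- quantify_and_filter(windows, ev, samples, models,
                           lib_sizes = c(s1 = 2e6, s2 = 2e6))
  tab <- q$table
  expect_equal(tab$PU_average.ctrl, c(25, 75))      # 10/40, 30/40
  expect_equal(tab$CE_average.ctrl, c(10, 30))
  # TPM = CE / 0.015 / (lib/1e6): 10/0.015/2
  expect_equal(tab$TPM_average.ctrl, c(10, 30) / 0.015 / 2)
  expect_equal(unique(tab$TPM_maximum.ctrl), 30 / 0.015 / 2)
})

test_that("the filter is strict: CE_average exactly 4 fails", {
  models <- toy_models()
  windows <- data.frame(window_id = "w1", contig = "chr1", strand = "+",
                        center = 450L, start = 443L, end = 457L,
                        n_events = 0L, gene_id = "gA",
                        stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = "s1", condition = "ctrl",
                        stringsAsFactors = FALSE)
  ev <- data.frame(contig = "chr1", strand = "+", position = 450L,
                   sample_id = "s1", count = 4L, stringsAsFactors = FALSE)
  q <- quantify_and_filter(windows, ev, samples, models,
                           lib_sizes = c(s1 = 1e6))
  expect_false(q$table$pass)                  # CE_average == 4, not > 4
  ev$count <- 5L
  q2 <- quantify_and_filter(windows, ev, samples, models,
                            lib_sizes = c(s1 = 1e6))
  expect_true(q2$table$pass)
})

test_that("genes with zero events are skipped with a warning", {
  models <- toy_models()
  windows <- data.frame(window_id = c("w1", "w2"), contig = "chr1",
                        strand = c("+", "-"), center = c(450L, 1100L),
                        start = c(443L, 1093L), end = c(457L, 1107L),
                        n_events = 0L, gene_id = c("gA", "gB"),
                        stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = "s1", condition = "ctrl",
                        stringsAsFactors = FALSE)
  ev <- data.frame(contig = "chr1", strand = "+", position = 450L,
                   sample_id = "s1", count = 10L,
                   stringsAsFactors = FALSE)
  expect_warning(q <- quantify_and_filter(windows, ev, samples, models,
                                          lib_sizes = c(s1 = 1e6)),
                 "zero")
  expect_identical(q$dropped_genes, "gB")
})

test_that("per-gene PU sums to at most 100", {
  set.seed(99)
  sim <- simulate_genome(n_genes = 8, seed = 99L)
  mace <- simulate_mace_reads(sim, reads_per_pas = 15, seed = 99L)
  pos <- data.frame(read_id = mace$reads$read_id,
                    contig = mace$reads$contig,
                    strand = mace$reads$strand,
                    position = mace$reads$read3p,
                    stringsAsFactors = FALSE)
  prep <- prepare_reads(mace$reads, pos)
  ev <- cleavage_events_from_reads(prep)
  cl <- cluster_cleavage_events(pool_events(ev))
  win <- define_pas_windows(cl)
  asg <- assign_gene_and_region(win, sim$models)
  q <- quantify_and_filter(asg$windows, ev, mace$samples, sim$models)
  pu <- q$table$PU_average.ctrl
  sums <- tapply(pu, q$table$gene_id, sum)
  expect_true(all(sums <= 100 + 1e-9))
})
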