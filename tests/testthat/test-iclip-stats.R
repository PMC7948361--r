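# iclip_stats: crosslink extraction, significant-site calling, k-mer
# z-scores, metaprofiles, two-library comparison.

mk_track <- function(positions, counts, strand = "+", lib = "L") {
  crosslink_track(lib, data.frame(
    contig = "chr1", strand = strand, position = positions,
    count = counts, stringsAsFactors = FALSE))
}

test_that("crosslink extraction uses the -1 truncation convention", {
  g <- toy_genome(chr1 = strrep("C", 200))
  rs <- data.frame(contig = "chr1", strand = c("+", "-", "+"),
                   start = c(100L, 100L, 100L), stringsAsFactors = FALSE)
  tr <- extract_crosslinks(rs, g)
  expect_setequal(tr$events$position, c(99L, 101L))
  expect_equal(tr$events$count[tr$events$position == 99L], 2L)
  expect_equal(tr$n_events, 3L)
  expect_equal(tr$n_positions, 2L)
})

test_that("off-contig crosslinks are dropped with a warning", {
  g <- toy_genome(chr1 = strrep("C", 50))
  rs <- data.frame(contig = "chr1", strand = c("+", "+", "-"),
                   start = c(1L, 10L, 50L), stringsAsFactors = FALSE)
  # "+" start 1 -> 0 and "-" start 50 -> 51 both fall off the contig
  expect_warning(tr <- extract_crosslinks(rs, g), "off-contig")
  expect_equal(tr$n_events, 1L)
  expect_equal(tr$events$position, 9L)
})

test_that("crosslink track validates counts and duplicates", {
  expect_error(mk_track(1L, 0L), ">= 1")
  expect_error(crosslink_track("L", data.frame(
    contig = "chr1", strand = "+", position = c(5L, 5L),
    count = c(1L, 2L))), "duplicate")
})

test_that("a single loaded position is called significant; uniform is not", {
  models <- gene_models(
    data.frame(gene_id = "g1", contig = "chr1", strand = "+",
               start = 1L, end = 1000L, stringsAsFactors = FALSE),
    data.frame(gene_id = "g1", kind = "3UTR", start = 1L, end = 1000L,
               stringsAsFactors = FALSE))
  spike <- mk_track(500L, 50L)
  res <- call_significant_xlinks(spike, models, n_perm = 50L, seed = 1L)
  expect_true(res$significant[res$position == 500L])

  unif <- mk_track(seq(10L, 990L, by = 20L), rep(1L, 50))
  res_u <- call_significant_xlinks(unif, models, n_perm = 50L, seed = 1L)
  expect_false(any(res_u$significant))
})

test_that("n_perm = 0 errors; genes with < 2 events yield no calls", {
  models <- gene_models(
    data.frame(gene_id = "g1", contig = "chr1", strand = "+",
               start = 1L, end = 100L, stringsAsFactors = FALSE),
    data.frame(gene_id = "g1", kind = "3UTR", start = 1L, end = 100L,
               stringsAsFactors = FALSE))
  tr <- mk_track(50L, 1L)
  expect_error(call_significant_xlinks(tr, models, n_perm = 0L), "perm")
  res <- call_significant_xlinks(tr, models)
  expect_false(any(res$significant))
})

test_that("permutation FDR respects the nominal level under the null", {
  # uniform-null calibration: called positions should be rare
  models <- gene_models(
    data.frame(gene_id = "g1", contig = "chr1", strand = "+",
               start = 1L, end = 2000L, stringsAsFactors = FALSE),
    data.frame(gene_id = "g1", kind = "3UTR", start = 1L, end = 2000L,
               stringsAsFactors = FALSE))
  frac <- vapply(1:25, function(s) {
    set.seed(s)
    pos <- sample.int(2000L, 150L, replace = TRUE)
    tb <- table(pos)
    tr <- mk_track(as.integer(names(tb)), as.integer(tb))
    res <- call_significant_xlinks(tr, models, n_perm = 40L, seed = s)
    mean(res$significant)
  }, numeric(1))
  expect_lt(mean(frac), 0.075)        # 1.5 x nominal 0.05
})

test_that("planted k-mer at a fixed flank offset ranks first", {
  set.seed(41)
  chars <- strsplit(rand_dna(6000), "")[[1]]
  sites <- data.frame(contig = "chr1", strand = "+",
                      position = seq(200L, 5800L, by = 160L),
                      gene_id = "g1", stringsAsFactors = FALSE)
  for (p in sites$position) chars[(p + 6):(p + 10)] <- c("T", "G", "T",
                                                         "A", "A")
  g <- toy_genome(chr1 = paste(chars, collapse = ""))
  models <- gene_models(
    data.frame(gene_id = "g1", contig = "chr1", strand = "+",
               start = 1L, end = 6000L, stringsAsFactors = FALSE),
    data.frame(gene_id = "g1", kind = "3UTR", start = 1L, end = 6000L,
               stringsAsFactors = FALSE))
  kz <- kmer_zscore(sites, g, models, k = 5L, n_shuffles = 30L,
                    seed = 2L)
  expect_identical(kz$kmer[1], "TGTAA")
  expect_equal(sum(kz$observed), attr(kz, "n_windows"))
  expect_identical(kz$rank, seq_len(nrow(kz)))
})

test_that("pas_metaprofile implements the two-step normalization", {
  # single anchor, single event at offset -75
  tr <- mk_track(c(925L, 2000L), c(4L, 1L))
  anchors <- data.frame(contig = "chr1", strand = "+", center = 1000L,
                        stringsAsFactors = FALSE)
  prof <- pas_metaprofile(tr, anchors)
  expect_equal(prof$raw[prof$offset == -75L], 4 / 1 / 2)
  expect_equal(sum(prof$raw), 2)
  # anchor duplication invariance
  prof2 <- pas_metaprofile(tr, rbind(anchors, anchors))
  expect_equal(prof2$raw, prof$raw)
  expect_error(pas_metaprofile(tr, anchors[0, ]), "empty")
})

test_that("profile scales by count ratio over position ratio", {
  # library B: same events split across twice the positions, half counts
  a <- mk_track(c(900L, 950L), c(4L, 4L))
  b <- mk_track(c(900L, 901L, 950L, 951L), c(2L, 2L, 2L, 2L))
  anchors <- data.frame(contig = "chr1", strand = "+", center = 1000L,
                        stringsAsFactors = FALSE)
  pa <- pas_metaprofile(a, anchors)
  pb <- pas_metaprofile(b, anchors)
  expect_equal(pb$raw[pb$offset == -100L],
               pa$raw[pa$offset == -100L] * (1 / 2) / 2)
})

test_that("two-proportions z matches the closed form to 1e-9", {
  expect_equal(two_proportions_z(30, 1000, 10, 1000),
               oracle_two_prop_z(30, 1000, 10, 1000), tolerance = 1e-12)
  expect_equal(round(two_proportions_z(30, 1000, 10, 1000), 2), 3.19)
  set.seed(43)
  for (i in 1:1000) {
    n1 <- sample(50:5000, 1); n2 <- sample(50:5000, 1)
    x1 <- sample.int(n1, 1) - 1L; x2 <- sample.int(n2, 1) - 1L
    z <- two_proportions_z(x1, n1, x2, n2)
    zo <- oracle_two_prop_z(x1, n1, x2, n2)
    if (is.na(zo) || !is.finite(zo)) next
    expect_equal(z, zo, tolerance = 1e-9)
  }
})

test_that("identical tracks compare to z = 0 with no flags", {
  tr <- mk_track(seq(900L, 1100L, by = 10L), rep(3L, 21))
  anchors <- data.frame(contig = "chr1", strand = "+", center = 1000L,
                        stringsAsFactors = FALSE)
  cmp <- compare_profiles(tr, tr, anchors, window = c(-150L, 150L))
  expect_true(all(cmp$table$z == 0))
  expect_false(any(cmp$table$flag))
  expect_equal(cmp$scaling_factor, 1)
})

test_that("comparison errors on zero totals and applies the scaling", {
  a <- mk_track(100L, 5L)
  anchors <- data.frame(contig = "chr1", strand = "+", center = 150L,
                        stringsAsFactors = FALSE)
  empty <- list(library = "E",
                events = data.frame(contig = character(),
                                    strand = character(),
                                    position = integer(),
                                    count = integer()),
                n_events = 0, n_positions = 0)
  class(empty) <- "crosslink_track"
  expect_error(compare_profiles(a, empty, anchors), "zero")

  b <- mk_track(c(100L, 120L), c(5L, 5L))
  cmp <- compare_profiles(a, b, anchors, window = c(-100L, 0L))
  expect_equal(cmp$scaling_factor, 1 / 2)
})

test_that("BH flags are monotone in the threshold", {
  set.seed(44)
  p <- runif(200)^2
  q <- pasatlas:::bh_adjust(p)
  expect_true(all(which(q <= 0.01) %in% which(q <= 0.05)))
  expect_identical(q, p.adjust(p, "BH"))
})

test_that("profile_background_z is seeded and excludes sd-0 offsets", {
  set.seed(45)
  pos <- sample.int(5000L, 400L)
  tr <- mk_track(sort(pos), rep(1L, length(pos)))
  pool <- data.frame(contig = "chr1", strand = "+",
                     center = seq(600L, 4400L, by = 40L),
                     stringsAsFactors = FALSE)
  target <- pool[1:15, ]
  r1 <- profile_background_z(target, pool, tr, window = c(-50L, 50L),
                             n_resamples = 25L, seed = 9L)
  r2 <- profile_background_z(target, pool, tr, window = c(-50L, 50L),
                             n_resamples = 25L, seed = 9L)
  expect_identical(r1, r2)
  expect_true(all(is.na(r1$z[r1$excluded])))
})
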