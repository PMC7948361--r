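# pas_annotation: gene/region assignment, s/p/o/d typing, CSE
# hierarchy, DaPars matching, APA sets, Fisher overlap.

win_at <- function(center, strand = "+", id = "w1") {
  data.frame(window_id = id, contig = "chr1", strand = strand,
             center = center, start = center - 7L, end = center + 7L,
             n_events = 1L, stringsAsFactors = FALSE)
}

test_that("centers are assigned by overlap; multi-gene centers removed", {
  m <- toy_models()
  res <- assign_gene_and_region(win_at(450L), m)
  expect_identical(res$windows$gene_id, "gA")
  expect_identical(res$windows$region, "3UTR")

  # overlapping genes: duplicate gA as gC
  genes2 <- rbind(m$genes,
                  data.frame(gene_id = "gC", contig = "chr1",
                             strand = "+", start = 101L, end = 600L))
  m2 <- gene_models(genes2, m$regions)
  res2 <- assign_gene_and_region(win_at(450L), m2)
  expect_equal(nrow(res2$windows), 0L)
  expect_equal(res2$n_removed_multi, 1L)
})

test_that("centers 1-50 nt downstream are pulled into the 3'UTR", {
  m <- toy_models()
  res <- assign_gene_and_region(win_at(630L), m)   # 30 nt past gA end
  expect_identical(res$windows$gene_id, "gA")
  expect_identical(res$windows$region, "3UTR")
  expect_equal(res$windows$distance_to_annotated_end, 30L)

  far <- assign_gene_and_region(win_at(700L), m)   # 100 nt past
  expect_equal(nrow(far$windows), 0L)
  expect_equal(far$n_removed_unassigned, 1L)

  # minus-strand gB: downstream = decreasing coordinate
  res_m <- assign_gene_and_region(win_at(980L, "-"), m)
  expect_identical(res_m$windows$gene_id, "gB")
  expect_identical(res_m$windows$region, "3UTR")
})

test_that("region precedence is 3UTR > intron > single kind > Other", {
  m <- toy_models()
  expect_identical(assign_gene_and_region(win_at(350L), m)$windows$region,
                   "intron")
  expect_identical(assign_gene_and_region(win_at(200L), m)$windows$region,
                   "CDS")
  expect_identical(assign_gene_and_region(win_at(120L), m)$windows$region,
                   "5UTR")
})

test_that("s/p/o/d typing follows transcription order", {
  rec <- data.frame(gene_id = "g", strand = "+",
                    center = c(500L, 800L, 1200L),
                    stringsAsFactors = FALSE)
  expect_identical(classify_pas_types(rec)$pas_type,
                   c("pPAS", "oPAS", "dPAS"))
  rec_m <- data.frame(gene_id = "g", strand = "-",
                      center = c(500L, 800L), stringsAsFactors = FALSE)
  t_m <- classify_pas_types(rec_m)
  expect_identical(t_m$pas_type[t_m$center == 800L], "pPAS")
  expect_identical(t_m$pas_type[t_m$center == 500L], "dPAS")
  one <- data.frame(gene_id = "g", strand = "+", center = 100L,
                    stringsAsFactors = FALSE)
  expect_identical(classify_pas_types(one)$pas_type, "sPAS")
})

test_that("type counts are conserved over 1,000 random gene layouts", {
  set.seed(7)
  for (case in 1:1000) {
    n_genes <- sample(1:5, 1)
    rec <- do.call(rbind, lapply(seq_len(n_genes), function(g) {
      n <- sample(1:4, 1)
      data.frame(gene_id = paste0("g", g),
                 strand = sample(c("+", "-"), 1),
                 center = sample(1:10000, n), stringsAsFactors = FALSE)
    }))
    ty <- classify_pas_types(rec)
    per <- split(ty$pas_type, ty$gene_id)
    for (p in per) {
      if (length(p) == 1) {
        expect_identical(p, "sPAS")
      } else {
        expect_equal(sum(p == "pPAS"), 1L)
        expect_equal(sum(p == "dPAS"), 1L)
        expect_equal(sum(p == "oPAS"), length(p) - 2L)
      }
    }
  }
})

test_that("CSE hierarchy: AAUAAA > AUUAAA > closest other", {
  hex <- cse_hexamers()
  # AATAAA at -20, ATTAAA at -40 -> AAUAAA
  s <- strsplit(strrep("C", 60), "")[[1]]
  s[(41 - 20):(46 - 20)] <- strsplit("AATAAA", "")[[1]]
  s[(41 - 40):(46 - 40)] <- strsplit("ATTAAA", "")[[1]]
  g <- toy_genome(chr1 = paste(s, collapse = ""))
  rec <- data.frame(contig = "chr1", strand = "+", center = 41L,
                    stringsAsFactors = FALSE)
  out <- assign_cse(rec, g, hex)
  expect_identical(out$cse, "AAUAAA")
  expect_equal(out$cse_offset, -20L)

  # only TATAAA -> UAUAAA
  s2 <- strsplit(strrep("C", 60), "")[[1]]
  s2[16:21] <- strsplit("TATAAA", "")[[1]]
  out2 <- assign_cse(rec, toy_genome(chr1 = paste(s2, collapse = "")),
                     hex)
  expect_identical(out2$cse, "UAUAAA")

  # nothing -> NA
  out3 <- assign_cse(rec, toy_genome(chr1 = strrep("C", 60)), hex)
  expect_true(is.na(out3$cse))
})

test_that("truncated CSE windows are scanned in their available part", {
  g <- toy_genome(chr1 = paste0(strrep("C", 4), "AATAAA",
                                strrep("C", 30)))
  rec <- data.frame(contig = "chr1", strand = "+", center = 20L,
                    stringsAsFactors = FALSE)
  out <- assign_cse(rec, g, cse_hexamers())
  expect_identical(out$cse, "AAUAAA")
  expect_true(out$cse_truncated)
})

test_that("CSE assignment equals a brute-force oracle on 1,000 windows", {
  hex <- cse_hexamers()
  set.seed(11)
  for (case in 1:1000) {
    strand <- sample(c("+", "-"), 1)
    w <- rand_dna(50)
    # embed so the tx window upstream of the center equals w
    if (strand == "+") {
      g <- toy_genome(chr1 = paste0("CC", w, "GG"))
      center <- 53L
    } else {
      g <- toy_genome(chr1 = paste0(
        "CC", as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(w))), "GG"))
      center <- 2L
    }
    rec <- data.frame(contig = "chr1", strand = strand, center = center,
                      stringsAsFactors = FALSE)
    out <- assign_cse(rec, g, hex)
    want <- oracle_cse(w, hex)
    expect_identical(out$cse, want)
  }
})

test_that("match_dapars applies the -250/+50 window, types and closeness", {
  rec <- data.frame(gene_id = "g1", pas_type = "pPAS", center = 1000L,
                    strand = "+", stringsAsFactors = FALSE)
  dp <- data.frame(gene_id = "g1", ppas = 900L, dpas = NA_integer_,
                   stringsAsFactors = FALSE)
  m <- match_dapars(dp, rec)
  expect_equal(nrow(m), 1L)
  expect_equal(m$distance, -100L)

  dp2 <- data.frame(gene_id = "g1", ppas = 1060L, dpas = NA_integer_,
                    stringsAsFactors = FALSE)
  expect_equal(nrow(match_dapars(dp2, rec)), 0L)

  dp3 <- data.frame(gene_id = c("g1", "g1"), ppas = c(950L, 980L),
                    dpas = NA_integer_, stringsAsFactors = FALSE)
  m3 <- match_dapars(dp3, rec)
  expect_equal(m3$dapars_pos, 980L)

  # never across types
  dp4 <- data.frame(gene_id = "g1", ppas = NA_integer_, dpas = 995L,
                    stringsAsFactors = FALSE)
  expect_equal(nrow(match_dapars(dp4, rec)), 0L)
})

test_that("match_dapars is strand-mirror symmetric", {
  rec <- data.frame(gene_id = "g1", pas_type = "dPAS", center = 1000L,
                    strand = "-", stringsAsFactors = FALSE)
  # on "-", upstream = larger coordinates: 1200 is 200 nt upstream
  dp <- data.frame(gene_id = "g1", ppas = NA_integer_, dpas = 1200L,
                   stringsAsFactors = FALSE)
  m <- match_dapars(dp, rec)
  expect_equal(m$distance, -200L)
  # 60 nt downstream on "-" (coordinate 940) is outside +50
  dp2 <- data.frame(gene_id = "g1", ppas = NA_integer_, dpas = 940L,
                    stringsAsFactors = FALSE)
  expect_equal(nrow(match_dapars(dp2, rec)), 0L)
})

test_that("APA thresholds are inclusive and the sets disjoint", {
  dp <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    delta_pdui = c(-0.2, -0.2, 0.05, -0.04),
    fdr = c(0.01, 0.5, 0.1, 0.01), stringsAsFactors = FALSE)
  s <- threshold_apa(dp)
  expect_identical(s$shortened, "a")
  expect_identical(s$lengthened, "c")
  expect_length(intersect(s$shortened, s$lengthened), 0L)
})

test_that("overlap_fisher reproduces exact hypergeometric cases", {
  u <- paste0("g", 1:20)
  full <- overlap_fisher(u[1:10], u[1:10], u)
  expect_equal(full$overlap, 10L)
  expect_lt(full$p_value, 1)

  # [[5,0],[0,5]] -> P = 2 / choose(10,5)
  u10 <- paste0("g", 1:10)
  r <- overlap_fisher(u10[1:5], u10[1:5], u10)
  expect_equal(r$p_value, 2 / choose(10, 5), tolerance = 1e-12)

  expect_error(overlap_fisher("a", "b", character(0)), "universe")
})
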