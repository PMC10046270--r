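test_that("variant TSV reading handles empty input, identity rows, and non-SNV skipping", {
  # header-only file
  empty <- write_tsv(make_variants()[0, ])
  v <- read_variant_table(empty)
  expect_equal(nrow(v), 0L)
  expect_equal(attr(v, "n_skipped"), 0L)

  # identity round-trip of a fully specified row
  one <- make_variants(case_id = "case1", chrom = "chr1", pos = 100,
                       ref = "C", alt = "T", vaf = 0.5, gene = "TERT",
                       pathogenic = TRUE, ctx5 = "A", ctx3 = "A")
  v <- read_variant_table(write_tsv(one))
  expect_equal(v, one, ignore_attr = TRUE)

  # 3 rows, one an insertion -> 2 records, skip count 1, insertion retained
  # in the non_snv side list
  df <- make_variants(ref = c("C", "C", "T"), alt = c("T", "CTT", "G"))
  v <- suppressMessages(read_variant_table(write_tsv(df)))
  expect_equal(nrow(v), 2L)
  expect_equal(attr(v, "n_skipped"), 1L)
  expect_equal(nrow(attr(v, "non_snv")), 1L)
})

test_that("variant records with out-of-range VAF are rejected and counted", {
  df <- make_variants(vaf = c(0.5, 1.5, -0.1, 0.2))
  v <- suppressMessages(read_variant_table(write_tsv(df)))
  expect_equal(nrow(v), 2L)
  expect_equal(attr(v, "n_rejected"), 2L)
  expect_error(read_variant_table(tempfile()), "no such file")
})

test_that("TSV round-trip preserves variant collections, including unknown contexts", {
  df <- make_variants(ref = c("C", "G", "T"), alt = c("A", "A", "C"),
                      ctx5 = c("A", NA, "G"), ctx3 = c("T", "C", NA),
                      vaf = c(0.1, 0.25, 0.9), pathogenic = c(TRUE, FALSE, TRUE))
  path <- tempfile(fileext = ".tsv")
  write_variant_table(df, path)
  back <- read_variant_table(path)
  expect_equal(back, df, ignore_attr = TRUE)
})

test_that("random variant tables never yield records violating invariants", {
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  for (rep_i in 1:10) {
    n <- sample(5:40, 1)
    df <- data.frame(
      case_id = "c1", chrom = "chr1", pos = sample(c(-5L, 1:1000), n, TRUE),
      ref = sample(c(bases, "CT", ""), n, TRUE),
      alt = sample(c(bases, "AG"), n, TRUE),
      vaf = round(runif(n, -0.3, 1.3), 3),
      gene = "G1", pathogenic = sample(c(TRUE, FALSE), n, TRUE),
      ctx5 = sample(c(bases, "."), n, TRUE),
      ctx3 = sample(c(bases, "."), n, TRUE), stringsAsFactors = FALSE)
    v <- suppressMessages(read_variant_table(write_tsv(df)))
    if (nrow(v)) {
      expect_true(all(v$ref != v$alt))
      expect_true(all(v$vaf >= 0 & v$vaf <= 1))
      expect_true(all(v$pos >= 1))
      expect_true(all(v$ref %in% bases & v$alt %in% bases))
    }
    expect_equal(nrow(v) + attr(v, "n_skipped") + attr(v, "n_rejected"),
                 nrow(df))
  }
})

test_that("VCF dialect takes VAF from AF when present, else from AD depths", {
  vcf_af <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AF,Number=A,Type=Float,Description="Allele fraction">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR",
    "chr1\t100\t.\tC\tT\t.\tPASS\t.\tGT:AF\t0/1:0.42",
    "chr1\t200\t.\tG\tGA\t.\tPASS\t.\tGT:AF\t0/1:0.30",
    "chr2\t300\t.\tT\tA\t.\tPASS\t.\tGT:AF\t0/1:0.10")
  p <- tempfile(fileext = ".vcf"); writeLines(vcf_af, p)
  v <- suppressMessages(read_variant_table(p, dialect = "vcf", case_id = "c9"))
  expect_equal(nrow(v), 2L)            # the insertion is skipped
  expect_equal(attr(v, "n_skipped"), 1L)
  expect_equal(v$vaf, c(0.42, 0.10))
  expect_equal(unique(v$case_id), "c9")

  vcf_ad <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:AD\t0/1:75,25")
  p2 <- tempfile(fileext = ".vcf"); writeLines(vcf_ad, p2)
  v2 <- read_variant_table(p2, dialect = "vcf")
  expect_equal(v2$vaf, 0.25)
})

test_that("signature matrix reading validates channels and preserves column order", {
  channels <- sbs96_channels()
  # one uniform signature
  df <- data.frame(Type = channels, SIG1 = rep(1 / 96, 96),
                   check.names = FALSE)
  sm <- read_signature_matrix(write_tsv(df))
  expect_equal(unname(sm$probs[1, ]), rep(1 / 96, 96))
  expect_equal(sm$signature_ids, "SIG1")

  # missing channel is fatal and named
  expect_error(read_signature_matrix(write_tsv(df[-5, ])),
               channels[5], fixed = TRUE)
  # duplicate channel is fatal
  dup <- rbind(df, df[1, ])
  expect_error(read_signature_matrix(write_tsv(dup)), "duplicated")
  # row sum off by more than 1e-4 is fatal with the offending id
  bad <- df; bad$SIG1[1] <- bad$SIG1[1] + 0.01
  expect_error(read_signature_matrix(write_tsv(bad)), "SIG1")

  # two signatures: ids kept in column order, rows renormalized
  df2 <- data.frame(Type = channels, B = rep(1 / 96, 96),
                    A = c(rep(1 / 48, 48), rep(0, 48)), check.names = FALSE)
  sm2 <- read_signature_matrix(write_tsv(df2))
  expect_equal(sm2$signature_ids, c("B", "A"))
  expect_equal(rowSums(sm2$probs), c(B = 1, A = 1))
})

test_that("segment reading validates invariants and supports 0-based starts", {
  segs <- data.frame(chrom = "chr5", start = c(1, 10, 100, 7),
                     end = c(1000000, 5, 200, 50),
                     cn_total = c(2, 2, 2, 1),
                     cn_minor = c(1, 1, 2, 1))
  # row 2: start > end; row 3: minor exceeds lesser allele; row 4: minor > total - minor
  v <- suppressMessages(read_segments(write_tsv(segs)))
  expect_equal(nrow(v), 1L)
  expect_equal(attr(v, "n_rejected"), 3L)
  expect_equal(v$end, 1000000L)

  zb <- data.frame(chrom = "chr1", start = 0, end = 100,
                   cn_total = 2, cn_minor = 0)
  v2 <- read_segments(write_tsv(zb), zero_based = TRUE)
  expect_equal(v2$start, 1L)
})

test_that("context extraction reads flanks off the reference and handles edges", {
  ref <- c(ctgA = "GACAT", ctgB = "TTGGC")
  expect_equal(extract_context("ctgA", 3, ref), list(ctx5 = "A", ctx3 = "A"))
  expect_equal(extract_context("ctgB", 3, ref), list(ctx5 = "T", ctx3 = "G"))
  edge <- extract_context("ctgA", 1, ref)
  expect_true(is.na(edge$ctx5))
  expect_equal(edge$ctx3, "A")
  expect_error(extract_context("ctgZ", 3, ref), "contig")

  # same answers through a DNAStringSet and add_context()
  dss <- Biostrings::DNAStringSet(ref)
  v <- make_variants(chrom = c("ctgA", "ctgB"), pos = c(3L, 3L),
                     ref = c("C", "G"), alt = c("T", "A"),
                     ctx5 = NA, ctx3 = NA)
  v2 <- add_context(v, dss)
  expect_equal(v2$ctx5, c("A", "T"))
  expect_equal(v2$ctx3, c("A", "G"))
})
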