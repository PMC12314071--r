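test_that("FASTA reading: names, wrapping, validation, duplicates", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s desc", "ACGT"), f)
  expect_equal(read_fasta(f), c(s = "ACGT"))

  writeLines(c(">wrapped", "acgt", "ACGT", "nnAC"), f)
  expect_equal(read_fasta(f), c(wrapped = "ACGTACGTNNAC"))

  writeLines(c(">bad", "ACXT"), f)
  expect_error(read_fasta(f), "position 3")

  writeLines(c(">a", "ACGT", ">a", "GGGG"), f)
  expect_error(read_fasta(f), "duplicate")

  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty")
})

test_that("FASTA round-trips through write_fasta", {
  withr::with_seed(5, {
    seqs <- setNames(replicate(3, random_seq(120)), c("chr1", "chr2", "chr3"))
    f <- withr::local_tempfile(fileext = ".fa")
    write_fasta(seqs, f)
    expect_equal(read_fasta(f), seqs)
  })
})

test_that("gene models parse from GFF3 with strand-aware anchors", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t1001\t2000\t.\t+\t.\tID=gplus",
    "chr1\tx\tmRNA\t1001\t2000\t.\t+\t.\tID=gplus.1;Parent=gplus",
    "chr1\tx\tfive_prime_UTR\t1001\t1100\t.\t+\t.\tID=u5;Parent=gplus.1",
    "chr1\tx\tCDS\t1101\t1900\t.\t+\t.\tID=c1;Parent=gplus.1",
    "chr1\tx\tthree_prime_UTR\t1901\t2000\t.\t+\t.\tID=u3;Parent=gplus.1",
    "chr1\tx\tgene\t5001\t6000\t.\t-\t.\tID=gminus",
    "chr1\tx\tmRNA\t5001\t6000\t.\t-\t.\tID=gminus.1;Parent=gminus",
    "chr1\tx\tCDS\t5101\t5900\t.\t-\t.\tID=c2;Parent=gminus.1"
  ), f)
  gm <- read_gene_models(f)
  plus <- gm[gm$gene_id == "gplus", ]
  expect_equal(plus$tss, 1001L)
  expect_equal(plus$translational_start, 1101L)
  expect_equal(plus$utr3_end, 2000L)
  minus <- gm[gm$gene_id == "gminus", ]
  # minus strand: TSS at the numerically larger end
  expect_equal(minus$tss, 6000L)
  expect_equal(minus$translational_start, 5900L)
  expect_equal(minus$utr3_end, 5001L)
})

test_that("mRNA without CDS is skipped with a warning", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t100\t900\t.\t+\t.\tID=ok",
    "chr1\tx\tmRNA\t100\t900\t.\t+\t.\tID=ok.1;Parent=ok",
    "chr1\tx\tCDS\t200\t800\t.\t+\t.\tID=c;Parent=ok.1",
    "chr1\tx\tgene\t2000\t2900\t.\t+\t.\tID=nocds",
    "chr1\tx\tmRNA\t2000\t2900\t.\t+\t.\tID=nocds.1;Parent=nocds"
  ), f)
  expect_warning(gm <- read_gene_models(f), "without CDS")
  expect_equal(gm$gene_id, "ok")
})

test_that("longest transcript is chosen as primary", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t100\t2000\t.\t+\t.\tID=g",
    "chr1\tx\tmRNA\t100\t1500\t.\t+\t.\tID=g.short;Parent=g",
    "chr1\tx\tCDS\t200\t1400\t.\t+\t.\tID=c1;Parent=g.short",
    "chr1\tx\tmRNA\t100\t2000\t.\t+\t.\tID=g.long;Parent=g",
    "chr1\tx\tCDS\t300\t1900\t.\t+\t.\tID=c2;Parent=g.long"
  ), f)
  gm <- read_gene_models(f)
  expect_equal(nrow(gm), 1)
  expect_equal(gm$translational_start, 300L)
  expect_equal(gm$utr3_end, 2000L)
})

test_that("JASPAR PFM and MEME minimal dialects parse and round-trip", {
  f <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(
    ">MA0001.1 test",
    "A [ 10 0 3 ]",
    "C [ 0 12 3 ]",
    "G [ 2 0 3 ]",
    "T [ 0 0 3 ]"
  ), f)
  lib <- read_motifs(f, "jaspar_pfm")
  expect_equal(lib$motif_id, "MA0001.1")
  expect_equal(lib$matrix[[1]],
               matrix(c(10, 0, 2, 0, 0, 12, 0, 0, 3, 3, 3, 3), 3, 4,
                      byrow = TRUE))

  # write and read back: identity
  f2 <- withr::local_tempfile(fileext = ".pfm")
  write_motifs(lib, f2)
  lib2 <- read_motifs(f2, "jaspar_pfm")
  expect_equal(lib2$matrix, lib$matrix)
  expect_equal(lib2$motif_id, lib$motif_id)

  fm <- withr::local_tempfile(fileext = ".meme")
  writeLines(c(
    "MEME version 4", "", "ALPHABET= ACGT", "",
    "MOTIF m1", "letter-probability matrix: alength= 4 w= 2 nsites= 20",
    " 0.5 0.2 0.2 0.1", " 0.25 0.25 0.25 0.25",
    "MOTIF m2", "letter-probability matrix: alength= 4 w= 1 nsites= 10",
    " 0.9 0.05 0.03 0.02"
  ), fm)
  ml <- read_motifs(fm, "meme_minimal")
  expect_equal(ml$motif_id, c("m1", "m2"))  # order preserved
  expect_equal(ml$matrix[[2]], matrix(c(0.9, 0.05, 0.03, 0.02), 1, 4))
})

test_that("malformed motif matrices are rejected", {
  lib_zero <- list(matrix(c(0, 0, 0, 0, 1, 1, 1, 1), 2, 4, byrow = TRUE))
  expect_error(motif_library("z", lib_zero), "all-zero")
  mixed <- list(matrix(c(0.5, 0.2, 0.2, 0.1, 10, 5, 3, 2), 2, 4,
                       byrow = TRUE))
  expect_error(motif_library("mx", mixed), "mix")
  expect_error(motif_library(c("a", "a"),
                             list(matrix(1, 1, 4), matrix(1, 1, 4))),
               "duplicate")
})

test_that("hit TSV writer sorts deterministically and round-trips", {
  hits <- tibble::tibble(
    motif_id = c("b", "a", "a"), family = "F",
    sequence_name = c("s1", "s1", "s1"),
    start = c(5L, 5L, 2L), stop = c(10L, 10L, 7L),
    strand = c("+", "-", "+"), score = c(1.5, 2.5, 3.5),
    p_value = c(1e-4, 1e-5, 1e-6),
    matched_sequence = c("AAAAAA", "CCCCCC", "GGGGGG")
  )
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(hits, f)
  back <- read_hits_tsv(f)
  # sorted by sequence_name, start, motif_id, strand
  expect_equal(back$start, c(2L, 5L, 5L))
  expect_equal(back$motif_id, c("a", "a", "b"))
  expect_equal(back$score, c(3.5, 2.5, 1.5))
  # empty hits -> header-only file
  write_hits_tsv(hits[0, ], f)
  expect_equal(nrow(read_hits_tsv(f)), 0)
  expect_equal(length(readLines(f)), 1)
})

test_that("BED DHS intervals convert to 1-based inclusive and back", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr1\t150\t250"), f)
  d <- read_dhs(f)
  expect_equal(d$start, c(1L, 151L))
  expect_equal(d$end, c(100L, 250L))
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_dhs(d, f2)
  expect_equal(readLines(f2), c("chr1\t0\t100", "chr1\t150\t250"))
})

test_that("family map reads and totalises", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("motif_id\tfamily", "m1\tWRKY", "m2\tDOF"), f)
  fm <- read_family_map(f)
  expect_equal(family_of(fm, c("m1", "m2", "m3")),
               c("WRKY", "DOF", "unassigned"))
})
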