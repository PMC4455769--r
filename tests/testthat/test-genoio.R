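test_that("VCF reading maps haploid and diploid GT codes, errors on junk", {
  d <- withr::local_tempdir()
  vcf <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
           "1H\t100\tm1\tA\tG\t.\t.\t.\tGT\t0\t1\t.",
           "1H\t200\tm2\tC\tT\t.\t.\t.\tGT\t0/1\t./.\t1/1")
  f <- file.path(d, "x.vcf")
  writeLines(vcf, f)
  g <- read_genotypes(f, "vcf")
  expect_identical(dim(g), c(3L, 2L))
  expect_identical(unname(g[, "m1"]), c(0L, 1L, NA_integer_))
  expect_identical(unname(g[, "m2"]), c(2L, NA_integer_, 1L))

  writeLines(c(vcf, "1H\t300\tm3\tA\tG\t.\t.\t.\tGT\t0\tX\t1"), f)
  expect_error(read_genotypes(f, "vcf"), "line 6")
})

test_that("TSV reading keeps H pre-QC and errors name the offending cell", {
  d <- withr::local_tempdir()
  f <- file.path(d, "g.tsv")
  writeLines(c("marker_id\tref\talt\ts1\ts2",
               "m1\tA\tG\tA\tH",
               "m2\tC\tT\tN\tT"), f)
  g <- read_genotypes(f, "tsv")
  expect_identical(unname(g["s2", ]), c(2L, 1L))
  expect_identical(unname(g["s1", ]), c(0L, NA_integer_))
  writeLines(c("marker_id\tref\talt\ts1\ts2",
               "m1\tA\tG\tA\tZ"), f)
  expect_error(read_genotypes(f, "tsv"), "s2")
})

test_that("qc_filter applies the three rules in order with exact boundaries", {
  # 20 samples, 6 markers: 1 monomorphic, 1 at exactly 15% missing (removed,
  # boundary is >=), 1 at 15% het (> 10%, removed), 3 clean
  n <- 20
  g <- matrix(0L, n, 6, dimnames = list(sprintf("s%02d", 1:n),
                                        paste0("m", 1:6)))
  g[, 2:6] <- rep(c(0L, 1L), length.out = n * 5)
  g[1:3, 2] <- NA                     # 3/20 = 15% missing
  g[1:3, 3] <- 2L                     # 15% het
  g[4, 4] <- NA                       # 5% missing: kept
  g[5, 5] <- 2L                       # 5% het: kept, converted to NA
  out <- qc_filter(g)
  expect_identical(out$report$monomorphic, 1L)
  expect_identical(out$report$missing, 1L)
  expect_identical(out$report$het, 1L)
  expect_identical(out$report$output, 3L)
  expect_identical(colnames(out$genotypes), c("m4", "m5", "m6"))
  expect_true(is.na(out$genotypes[5, "m5"]))            # residual H -> N
  expect_false(any(out$genotypes == 2L, na.rm = TRUE))
  # idempotence
  again <- qc_filter(out$genotypes)
  expect_identical(again$genotypes, out$genotypes)
  expect_identical(again$report$output, out$report$output)
  # all markers removed is an explicit error
  expect_error(qc_filter(matrix(1L, 4, 2)), "all markers")
})

test_that("polarize flips alt-ancestral markers, flags the rest, and is an involution", {
  g <- matrix(c(0L, 1L, 0L, 1L,
                1L, 1L, 0L, 0L,
                0L, 0L, 1L, 1L), 4, 3,
              dimnames = list(paste0("s", 1:4), paste0("m", 1:3)))
  mk <- data.frame(marker_id = paste0("m", 1:3),
                   ref = c("A", "A", "A"), alt = c("G", "G", "G"),
                   ancestral_state = c("G", NA, "C"),
                   stringsAsFactors = FALSE)
  p <- polarize(g, mk)
  expect_identical(unname(p[, "m1"]), unname(1L - g[, "m1"]))   # flipped
  expect_identical(unname(p[, "m2"]), unname(g[, "m2"]))        # untouched
  expect_identical(unname(attr(p, "polarized")), c(TRUE, FALSE, FALSE))
  expect_identical(unname(attr(p, "unpolarizable")), c(FALSE, FALSE, TRUE))
  # involution: flipping ancestral to the other allele restores the coding
  mk2 <- mk; mk2$ancestral_state[1] <- "A"
  p2 <- polarize(`attributes<-`(p, attributes(g)), mk2)
  expect_identical(unname(p2[, "m1"]), unname(p[, "m1"]))
})

test_that("simulated markers polarize consistently with generator truth", {
  b <- sim_small()
  g <- qc_geno(b)
  p <- polarize(g, b$markers)
  pol <- attr(p, "polarized")
  flip <- b$truth$flip[colnames(g)]
  # where polarized, code 0 must be the ancestral allele: generator truth says
  # ref is ancestral iff !flip, so flipped-coding markers must get flipped back
  anc <- b$markers$ancestral_state[match(colnames(g), b$markers$marker_id)]
  third <- !is.na(anc) &
    anc != b$markers$ref[match(colnames(g), b$markers$marker_id)] &
    anc != b$markers$alt[match(colnames(g), b$markers$marker_id)]
  expect_identical(unname(pol), unname(!is.na(anc) & !third))
  idx <- which(pol & flip)
  expect_true(all(p[, idx] == 1L - g[, idx], na.rm = TRUE))
  idx0 <- which(pol & !flip)
  expect_true(all(p[, idx0] == g[, idx0], na.rm = TRUE))
})

test_that("build_haplotypes windows, trailing drop, and code bijection", {
  b <- sim_small()
  g <- qc_geno(b)
  mk <- b$markers[b$markers$marker_id %in% colnames(g), ]
  hb <- build_haplotypes(g, b$markers)
  per_lg <- table(mk$linkage_group) %/% 5
  expect_equal(ncol(hb$codes), sum(per_lg), ignore_attr = TRUE)
  # bijection within a window: same code iff same 5-SNP string
  w <- 1L
  mem <- hb$members[[w]]
  strs <- apply(g[, mem], 1, function(r)
    if (anyNA(r)) NA else paste(r, collapse = ""))
  codes <- hb$codes[, w]
  for (s in unique(stats::na.omit(strs))) {
    expect_length(unique(codes[which(strs == s)]), 1L)
  }
  expect_identical(is.na(codes), is.na(strs))
  expect_identical(length(hb$strings[[w]]),
                   length(unique(stats::na.omit(strs))))
})

test_that("build_haplotypes trailing-drop rule and short-group warning", {
  g <- matrix(rep(c(0L, 1L), 30), 5, 12,
              dimnames = list(paste0("s", 1:5), paste0("m", sprintf("%02d", 1:12))))
  mk <- toy_markers(g)
  hb <- build_haplotypes(g, mk)
  expect_identical(ncol(hb$codes), 2L)     # 12 markers -> 2 windows, 2 dropped
  mk2 <- mk; mk2$linkage_group <- c(rep("1H", 10), "2H", "2H")
  expect_warning(hb2 <- build_haplotypes(g, mk2), "fewer than 5")
  expect_identical(ncol(hb2$codes), 2L)
})

test_that("cluster_mode imputation fills missing calls with the cluster mode", {
  g <- matrix(c(1L, 1L, 1L, NA, 0L, 0L, 0L, 0L), 8, 5,
              dimnames = list(paste0("s", 1:8), paste0("m", 1:5)))
  g[, 2:5] <- rep(0:1, 20)[1:32]
  cl <- factor(rep(c("a", "b"), each = 4))
  hb <- build_haplotypes(g, toy_markers(g), impute = "cluster_mode",
                         clusters = cl)
  expect_false(anyNA(hb$codes))
  expect_error(build_haplotypes(g, toy_markers(g), impute = "cluster_mode"),
               "clusters")
})
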