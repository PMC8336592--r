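# Fixtures are written in-code; VCF bodies stay tiny and uncompressed.

write_vcf_fixture <- function(records, path, contig = "ref", contig_len = 60) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contig, contig_len),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    records
  ), path)
}

ref60 <- function() {
  withr::with_seed(5, rand_dna(60))
}

test_that("VCF alleles are split, de-anchored and converted to 0-based", {
  ref <- ref60()
  rb <- function(i) substr(ref, i, i) # 1-based base
  alt1 <- setdiff(c("A", "C", "G", "T"), rb(5))[1]
  recs <- c(
    sprintf("ref\t5\t.\t%s\t%s\t.\tPASS\t.", rb(5), alt1), # SNP at coordinate 4
    sprintf("ref\t10\t.\t%s\t%s\t.\tPASS\t.", substr(ref, 10, 13), rb(10)), # DEL span 3 at 10
    sprintf("ref\t20\t.\t%s\t%sTTA\t.\tPASS\t.", rb(20), rb(20)), # INS TTA at 20
    sprintf("ref\t30\t.\t%s\t%s\t.\tPASS\t.", rb(30), rb(30)) # non-variant, skipped
  )
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(recs, f)
  names(ref) <- "ref"
  rv <- read_variants(f, ref)
  v <- rv$variants
  expect_equal(v$coordinate[v$vtype == "SNP"], 4)
  expect_equal(v$allele[v$vtype == "SNP"], alt1)
  expect_equal(v$coordinate[v$vtype == "DEL"], 10)
  expect_equal(v$span[v$vtype == "DEL"], 3)
  expect_equal(v$coordinate[v$vtype == "INS"], 20)
  expect_equal(v$allele[v$vtype == "INS"], "TTA")
  expect_equal(rv$stats$n_records, 4)
  expect_equal(rv$stats$n_alleles_kept, 3)
  expect_equal(rv$stats$n_skipped_other, 1)
})

test_that("multi-allelic records become one row per alternative allele", {
  ref <- ref60()
  rb <- function(i) substr(ref, i, i)
  alts <- setdiff(c("A", "C", "G", "T"), rb(8))
  recs <- sprintf("ref\t8\t.\t%s\t%s\t.\tPASS\t.", rb(8), paste(alts[1:2], collapse = ","))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(recs, f)
  names(ref) <- "ref"
  rv <- read_variants(f, ref)
  expect_equal(nrow(rv$variants), 2)
  expect_setequal(rv$variants$allele, alts[1:2])
})

test_that("REF disagreement with the reference is an error naming the locus", {
  ref <- ref60()
  bad <- setdiff(c("A", "C", "G", "T"), substr(ref, 12, 12))[1]
  alt <- setdiff(c("A", "C", "G", "T"), bad)[1]
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(sprintf("ref\t12\t.\t%s\t%s\t.\tPASS\t.", bad, alt), f)
  names(ref) <- "ref"
  expect_error(read_variants(f, ref), "REF mismatch at ref:12")
})

test_that("symbolic SVs resolve via SVLEN/END; unsupported classes are counted", {
  ref <- ref60()
  rb <- function(i) substr(ref, i, i)
  recs <- c(
    sprintf("ref\t6\t.\t%s\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=16", rb(6)), # span 10
    sprintf("ref\t25\t.\t%s\t<INS>\t.\tPASS\tSVLEN=12", rb(25)),
    sprintf("ref\t40\t.\t%s\t<INV>\t.\tPASS\tEND=50", rb(40))
  )
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(recs, f)
  names(ref) <- "ref"
  rv <- read_variants(f, ref)
  expect_equal(rv$stats$n_skipped_non_indel_sv, 1)
  del <- rv$variants[rv$variants$vtype == "DEL", ]
  expect_equal(del$coordinate, 6)
  expect_equal(del$span, 10)
  ins <- rv$variants[rv$variants$vtype == "INS", ]
  expect_equal(nchar(ins$allele), 12)
})

test_that("SV mode keeps only indels at or above the length floor", {
  ref <- ref60()
  rb <- function(i) substr(ref, i, i)
  alt1 <- setdiff(c("A", "C", "G", "T"), rb(3))[1]
  recs <- c(
    sprintf("ref\t3\t.\t%s\t%s\t.\tPASS\t.", rb(3), alt1), # SNP
    sprintf("ref\t7\t.\t%s\t%s%s\t.\tPASS\t.", rb(7), rb(7), strrep("A", 4)), # short INS
    sprintf("ref\t15\t.\t%s\t<DEL>\t.\tPASS\tSVLEN=-40", rb(15)) # SV deletion
  )
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(recs, f)
  names(ref) <- "ref"
  rv <- read_variants(f, ref, min_sv_len = 50)
  expect_equal(nrow(rv$variants), 0)
  rv2 <- read_variants(f, ref, min_sv_len = 30)
  expect_equal(rv2$variants$vtype, "DEL")
  expect_equal(rv2$variants$span, 40)
})

test_that("records on other contigs are skipped with a count", {
  ref <- ref60()
  rb <- function(i) substr(ref, i, i)
  alt1 <- setdiff(c("A", "C", "G", "T"), rb(3))[1]
  recs <- c(
    sprintf("ref\t3\t.\t%s\t%s\t.\tPASS\t.", rb(3), alt1),
    "chrOther\t5\t.\tA\tT\t.\tPASS\t."
  )
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(recs, f)
  names(ref) <- "ref"
  rv <- read_variants(f, ref)
  expect_equal(nrow(rv$variants), 1)
  expect_equal(rv$stats$n_skipped_other, 1)
})

test_that("write then read round-trips the retained variant tuples", {
  sim <- simulate_variation(sim_spec(800, snp_rate = 0.02, indel_rate = 0.01,
    sv_count = 2, sv_len_min = 50, sv_len_max = 120, seed = 21
  ))
  g <- build_variation_graph(sim$reference, sim$variants)
  fa <- withr::local_tempfile(fileext = ".fa")
  vc <- withr::local_tempfile(fileext = ".vcf")
  write_catalogue(sim$reference, sim$variants, fasta_out = fa, vcf_out = vc)
  ref2 <- read_reference_fasta(fa)
  expect_equal(unname(ref2), sim$reference)
  rv <- read_variants(vc, ref2)
  expect_equal(
    rv$variants[order(rv$variants$coordinate, rv$variants$vtype, rv$variants$allele), ],
    g$variants[order(g$variants$coordinate, g$variants$vtype, g$variants$allele), ],
    ignore_attr = TRUE
  )
})

test_that("selection reports list every locus with its decision", {
  g <- build_variation_graph(
    ref60(),
    variants(c(5, 15, 25), rep("SNP", 3),
      vapply(c(5, 15, 25), function(c0) {
        setdiff(c("A", "C", "G", "T"), substr(ref60(), c0 + 1, c0 + 1))[1]
      }, character(1))
    )
  )
  sel <- greedy_snp(g, alpha = 40, delta = 1)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  rpt <- withr::local_tempfile(fileext = ".tsv")
  write_selection(sel, g, vcf_out = vcf, report_out = rpt)
  lines <- readLines(rpt)
  expect_length(grep("^# ", lines), 2)
  body <- utils::read.delim(text = lines[!grepl("^# ", lines)])
  expect_equal(nrow(body), 3)
  expect_setequal(unique(body$decision), c("keep", "drop"))
  expect_equal(sum(body$decision == "drop"), 1)
  # retained-only VCF
  vcf_body <- grep("^[^#]", readLines(vcf), value = TRUE)
  expect_length(vcf_body, 2)
  # remove-all writes a header-only VCF
  all_rm <- apply_selection(g, integer())
  sel_all <- structure(sel, class = class(sel))
  sel_all$removed_coordinates <- g$loci$coordinate
  vcf2 <- withr::local_tempfile(fileext = ".vcf")
  write_selection(sel_all, g, vcf_out = vcf2)
  expect_length(grep("^[^#]", readLines(vcf2)), 0)
})
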