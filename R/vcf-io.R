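# FASTA/VCF boundary. All coordinates inside the package are 0-based
# half-open; VCF's 1-based anchored POS is converted here and nowhere else.

#' Read a reference sequence from FASTA
#'
#' @param path FASTA file (one or more sequences).
#' @param contig Sequence name to select; default first sequence. Matching is
#'   on the first whitespace-delimited token of the header.
#' @return A named character string (name = contig).
#' @export
read_reference_fasta <- function(path, contig = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  if (is.null(contig)) {
    pick <- 1L
  } else {
    pick <- match(contig, ids)
    if (is.na(pick)) {
      abort(sprintf("contig '%s' not found in %s", contig, path))
    }
  }
  out <- toupper(as.character(seqs[[pick]]))
  names(out) <- ids[pick]
  out
}

info_field <- function(info, key) {
  if (is.na(info)) {
    return(NA_character_)
  }
  m <- regexpr(paste0("(?:^|;)", key, "=([^;]*)"), info, perl = TRUE)
  if (m == -1) {
    return(NA_character_)
  }
  hit <- regmatches(info, m)
  sub(paste0("^;?", key, "="), "", hit)
}

parse_one_alt <- function(pos, ref, alt, info) {
  # returns list(vtype, coordinate, allele, span) or a skip marker
  if (grepl("^<", alt)) {
    if (alt %in% c("<DEL>", "<INS>")) {
      svlen <- suppressWarnings(as.numeric(info_field(info, "SVLEN")))
      endv <- suppressWarnings(as.numeric(info_field(info, "END")))
      len <- if (!is.na(svlen)) abs(svlen) else if (!is.na(endv)) endv - pos else NA
      if (is.na(len) || len < 1) {
        return(list(skip = "other"))
      }
      if (alt == "<DEL>") {
        return(list(vtype = "DEL", coordinate = pos, allele = "", span = as.integer(len)))
      }
      # symbolic insertion: the sequence is unknown, stand in with N's
      return(list(
        vtype = "INS", coordinate = pos,
        allele = strrep("N", as.integer(len)), span = 0L
      ))
    }
    return(list(skip = "non_indel_sv")) # <INV>, <DUP>, <CNV>, <BND>, ...
  }
  if (!grepl("^[ACGTNacgtn]+$", alt)) {
    return(list(skip = "other"))
  }
  r <- nchar(ref)
  a <- nchar(alt)
  if (r == 1 && a == 1) {
    if (toupper(alt) == toupper(ref)) {
      return(list(skip = "other"))
    }
    return(list(vtype = "SNP", coordinate = pos - 1L, allele = toupper(alt), span = 1L))
  }
  ref_u <- toupper(ref)
  alt_u <- toupper(alt)
  if (a == 1 && r > 1) {
    if (substr(ref_u, 1, 1) == alt_u) { # leading anchor base
      return(list(vtype = "DEL", coordinate = pos, allele = "", span = r - 1L))
    }
    if (pos == 1 && substr(ref_u, r, r) == alt_u) { # trailing anchor at POS 1
      return(list(vtype = "DEL", coordinate = 0L, allele = "", span = r - 1L))
    }
    return(list(skip = "other"))
  }
  if (r == 1 && a > 1) {
    if (substr(alt_u, 1, 1) == ref_u) {
      return(list(
        vtype = "INS", coordinate = pos, allele = substr(alt_u, 2, a), span = 0L
      ))
    }
    if (pos == 1 && substr(alt_u, a, a) == ref_u) {
      return(list(
        vtype = "INS", coordinate = 0L, allele = substr(alt_u, 1, a - 1L), span = 0L
      ))
    }
    return(list(skip = "other"))
  }
  list(skip = "other") # complex/mixed allele
}

#' Read a variant catalogue from VCF
#'
#' Splits multi-allelic records, de-anchors indels (a record `POS REF=ACCT
#' ALT=A` becomes a deletion of span 3 at 0-based coordinate `POS`),
#' validates every REF field against the reference sequence, and optionally
#' restricts to structural variants. Symbolic `<DEL>`/`<INS>` alleles are
#' accepted when an `SVLEN` or `END` INFO field resolves their length (a
#' symbolic insertion's unknown sequence is stood in by `N`s); other symbolic
#' SV classes are counted and skipped, as are complex alleles and records on
#' other contigs. Unsorted input is tolerated.
#'
#' @param vcf_path Path to a VCF 4.x file (plain or bgzipped).
#' @param reference Reference string (as from [read_reference_fasta()]) the
#'   coordinates refer to.
#' @param contig Restrict to records on this CHROM; default: the name of
#'   `reference` if set, else all records.
#' @param min_sv_len If set, keep only insertions/deletions of at least this
#'   length (SV mode); everything smaller, including SNPs, is counted as
#'   skipped.
#' @return A list with `variants` (tibble, sorted, deduplicated) and `stats`
#'   (one-row tibble: `n_records`, `n_alleles_kept`, `n_skipped_non_indel_sv`,
#'   `n_skipped_other`).
#' @export
read_variants <- function(vcf_path, reference, contig = NULL, min_sv_len = NULL) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  info <- vcf@fix[, "INFO"]
  if (is.null(contig) && !is.null(names(reference))) contig <- names(reference)
  ref_str <- as_reference_string(reference)

  n_records <- nrow(fix)
  kept <- list()
  n_non_indel_sv <- 0L
  n_other <- 0L
  ki <- 0L
  for (r in seq_len(n_records)) {
    if (!is.null(contig) && fix[r, "CHROM"] != contig) {
      n_other <- n_other + 1L
      next
    }
    pos <- as.integer(fix[r, "POS"])
    ref <- fix[r, "REF"]
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    if (grepl("^[ACGTNacgtn]+$", ref)) {
      seen <- toupper(substr(ref_str, pos, pos + nchar(ref) - 1L))
      if (seen != toupper(ref)) {
        abort(sprintf(
          "VCF REF mismatch at %s:%d: file has '%s', reference has '%s'",
          fix[r, "CHROM"], pos, ref, seen
        ))
      }
    }
    for (alt in alts) {
      p <- parse_one_alt(pos, ref, alt, info[r])
      if (!is.null(p$skip)) {
        if (p$skip == "non_indel_sv") {
          n_non_indel_sv <- n_non_indel_sv + 1L
        } else {
          n_other <- n_other + 1L
        }
        next
      }
      if (!is.null(min_sv_len)) {
        len <- if (p$vtype == "DEL") p$span else nchar(p$allele)
        if (p$vtype == "SNP" || len < min_sv_len) {
          n_other <- n_other + 1L
          next
        }
      }
      ki <- ki + 1L
      kept[[ki]] <- p
    }
  }
  v <- if (ki > 0) {
    tibble(
      coordinate = vapply(kept, function(x) as.integer(x$coordinate), integer(1)),
      vtype = vapply(kept, `[[`, character(1), "vtype"),
      allele = vapply(kept, `[[`, character(1), "allele"),
      span = vapply(kept, function(x) as.integer(x$span), integer(1))
    )
  } else {
    variants()
  }
  v <- distinct(arrange(v, .data$coordinate, .data$vtype, .data$allele, .data$span))
  list(
    variants = v,
    stats = tibble(
      n_records = n_records,
      n_alleles_kept = nrow(v),
      n_skipped_non_indel_sv = n_non_indel_sv,
      n_skipped_other = n_other
    )
  )
}

vcf_record_for <- function(ref_str, coordinate, vtype, allele, span) {
  base_at <- function(i) substr(ref_str, i, i) # 1-based
  if (vtype == "SNP") {
    return(c(coordinate + 1L, base_at(coordinate + 1L), allele))
  }
  if (vtype == "INS") {
    if (coordinate == 0L) { # trailing-anchor convention at the left edge
      return(c(1L, base_at(1L), paste0(allele, base_at(1L))))
    }
    return(c(coordinate, base_at(coordinate), paste0(base_at(coordinate), allele)))
  }
  # DEL
  if (coordinate == 0L) {
    return(c(
      1L, substr(ref_str, 1L, span + 1L), base_at(span + 1L)
    ))
  }
  c(
    coordinate, substr(ref_str, coordinate, coordinate + span), base_at(coordinate)
  )
}

#' Write the retained variants and a per-locus selection report
#'
#' Emits a plain-text VCF holding exactly the retained variants (normalized,
#' left-anchored records synthesized from the graph) and a TSV report with
#' one row per locus: `coordinate`, `n_variants`, `penalty`, `decision`,
#' preceded by `#`-prefixed header lines stating algorithm, alpha, delta and
#' totals.
#'
#' @param result A `variant_selection`.
#' @param graph The `variation_graph` the selection was computed on.
#' @param vcf_out Path for the VCF of retained variants (`NULL` to skip).
#' @param report_out Path for the TSV report (`NULL` to skip).
#' @param contig CHROM value for emitted records; default `"ref"` or the
#'   reference name when known.
#' @return Invisibly, the report tibble.
#' @export
write_selection <- function(result, graph, vcf_out = NULL, report_out = NULL,
                            contig = NULL) {
  stopifnot(inherits(result, "variant_selection"), inherits(graph, "variation_graph"))
  if (is.null(contig)) contig <- "ref"
  if (!is.null(vcf_out)) {
    keep <- graph$variants[
      !(graph$variants$coordinate %in% result$removed_coordinates),
    ]
    recs <- character(nrow(keep))
    for (i in seq_len(nrow(keep))) {
      f <- vcf_record_for(
        graph$reference, keep$coordinate[i], keep$vtype[i],
        keep$allele[i], keep$span[i]
      )
      recs[i] <- paste(contig, f[1], ".", f[2], f[3], ".", "PASS", ".", sep = "\t")
    }
    # records must be position-sorted; indel anchoring can perturb order
    if (nrow(keep) > 0) recs <- recs[order(as.integer(vapply(strsplit(recs, "\t"), `[`, character(1), 2)))]
    writeLines(
      c(
        "##fileformat=VCFv4.2",
        sprintf("##contig=<ID=%s,length=%d>", contig, graph$length),
        sprintf(
          "##source=vgsieve %s alpha=%d delta=%d", result$algorithm,
          result$alpha, result$delta
        ),
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
        recs
      ),
      vcf_out
    )
  }
  report <- tidy(result)
  if (!is.null(report_out)) {
    hdr <- c(
      sprintf("# algorithm=%s alpha=%d delta=%d", result$algorithm, result$alpha, result$delta),
      sprintf(
        "# loci_total=%d loci_removed=%d variants_total=%d variants_removed=%d",
        result$total_locus_count, result$removed_locus_count,
        result$total_variant_count, result$removed_variant_count
      )
    )
    con <- file(report_out, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(paste(names(report), collapse = "\t"), con)
    if (nrow(report) > 0) {
      writeLines(do.call(paste, c(as.list(report), sep = "\t")), con)
    }
  }
  invisible(report)
}

#' Write a reference and variant catalogue as FASTA + VCF
#'
#' Companion to [simulate_variation()]: persists a simulated (or any)
#' reference/variant pair in standard formats.
#'
#' @param reference Reference string.
#' @param variants Variant tibble.
#' @param fasta_out,vcf_out Output paths (`NULL` to skip either).
#' @param contig Sequence/CHROM name, default `"ref"`.
#' @return Invisibly `NULL`.
#' @export
write_catalogue <- function(reference, variants, fasta_out = NULL, vcf_out = NULL,
                            contig = "ref") {
  ref_str <- as_reference_string(reference)
  if (!is.null(fasta_out)) {
    dss <- Biostrings::DNAStringSet(ref_str)
    names(dss) <- contig
    Biostrings::writeXStringSet(dss, fasta_out)
  }
  if (!is.null(vcf_out)) {
    g <- build_variation_graph(ref_str, variants)
    all_kept <- new_selection_result(g, integer(), "identity", 1L, 0L)
    write_selection(all_kept, g, vcf_out = vcf_out, contig = contig)
  }
  invisible(NULL)
}
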