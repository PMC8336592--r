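#' Assemble a variant tibble
#'
#' Convenience constructor for the tabular variant representation used across
#' the package. Each row is one alternative allele anchored at one reference
#' coordinate. Coordinates are 0-based offsets of the backbone vertex the
#' variant's first deviating edge leaves from; a deletion's `span` counts the
#' skipped reference bases and an insertion's `allele` holds the inserted
#' sequence.
#'
#' @param coordinate Integer vector of 0-based coordinates.
#' @param vtype Character vector, each one of `"SNP"`, `"INS"`, `"DEL"`.
#' @param allele Character vector: the alternative base (SNP), the inserted
#'   sequence (INS), or `""` (DEL).
#' @param span Integer vector: reference bases replaced/skipped. Defaults to
#'   1 for SNPs, 0 for insertions; deletions must state their span.
#' @return A tibble with columns `coordinate`, `vtype`, `allele`, `span`.
#' @export
#' @examples
#' variants(c(3, 7), c("SNP", "DEL"), c("A", ""), c(1, 4))
variants <- function(coordinate = integer(), vtype = character(),
                     allele = character(), span = NULL) {
  if (is.null(span)) {
    span <- ifelse(vtype == "SNP", 1L, ifelse(vtype == "INS", 0L, NA_integer_))
  }
  tibble(
    coordinate = as.integer(coordinate),
    vtype = as.character(vtype),
    allele = toupper(as.character(allele)),
    span = as.integer(span)
  )
}

expected_span <- function(vtype, span) {
  ifelse(vtype == "SNP", 1L, ifelse(vtype == "INS", 0L, span))
}

validate_variants <- function(variants, ref, lenient = FALSE) {
  needed <- c("coordinate", "vtype", "allele", "span")
  missing <- setdiff(needed, names(variants))
  if (length(missing) > 0) {
    abort(paste0("variant table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  v <- as_tibble(variants)[needed]
  v$coordinate <- as.integer(v$coordinate)
  v$allele <- toupper(as.character(v$allele))
  v$span <- as.integer(expected_span(v$vtype, v$span))
  bad_type <- !v$vtype %in% c("SNP", "INS", "DEL")
  if (any(bad_type)) {
    abort(paste0("unknown variant type(s): ", paste(unique(v$vtype[bad_type]), collapse = ", ")))
  }
  L <- nchar(ref)

  oob <- (v$vtype == "SNP" & (v$coordinate < 0L | v$coordinate >= L)) |
    (v$vtype == "INS" & (v$coordinate < 0L | v$coordinate > L)) |
    (v$vtype == "DEL" & (v$coordinate < 0L | v$span < 1L | v$coordinate + v$span > L))
  if (any(oob)) {
    i <- which(oob)[1]
    abort(sprintf(
      "variant out of reference bounds: %s at coordinate %d (span %d, reference length %d)",
      v$vtype[i], v$coordinate[i], v$span[i], L
    ))
  }

  is_snp <- v$vtype == "SNP"
  if (any(is_snp)) {
    if (any(nchar(v$allele[is_snp]) != 1L)) {
      abort("SNP alleles must be a single base")
    }
    refbase <- substring(ref, v$coordinate[is_snp] + 1L, v$coordinate[is_snp] + 1L)
    degenerate <- v$allele[is_snp] == refbase
    if (any(degenerate)) {
      i <- which(is_snp)[which(degenerate)[1]]
      msg <- sprintf(
        "SNP at coordinate %d equals the reference base '%s'",
        v$coordinate[i], v$allele[i]
      )
      if (lenient) {
        warn(paste0(msg, "; record skipped"))
        keep <- rep(TRUE, nrow(v))
        keep[which(is_snp)[degenerate]] <- FALSE
        v <- v[keep, ]
      } else {
        abort(msg)
      }
    }
  }
  if (any(v$vtype == "INS" & nchar(v$allele) < 1L)) {
    abort("insertion alleles must be non-empty")
  }
  v$allele[v$vtype == "DEL"] <- ""
  distinct(v)
}

#' Build a variation graph from a reference and a variant table
#'
#' The graph is the reference backbone of `nchar(reference) + 1` ordered
#' coordinate vertices augmented with one locus per coordinate that carries at
#' least one alternative allele. SNPs are parallel labeled edges between
#' adjacent vertices, deletions are epsilon-labeled skip edges and insertions
#' are labeled chains leaving and re-entering their host vertex. Identical
#' (coordinate, type, allele, span) records are deduplicated.
#'
#' @param reference Reference sequence: a character scalar over `{A,C,G,T,N}`
#'   or a `Biostrings::DNAString`/`DNAStringSet` (first sequence is used).
#' @param variants A variant tibble as produced by [variants()] or
#'   [read_variants()]; may be unsorted.
#' @param lenient If `TRUE`, SNP records equal to the reference base are
#'   skipped with a warning instead of raising an error.
#' @return An object of class `variation_graph`: a list with `reference`
#'   (string), `length`, the deduplicated `variants` tibble sorted by
#'   coordinate, and a per-locus tibble `loci` with derived columns
#'   `n_variants`, `delta_ins`, `delta_del`, `has_snp`, `has_ins`, `has_del`
#'   and `penalty` (see [locus_penalty()]).
#' @export
#' @examples
#' g <- build_variation_graph("ACGTACGT", variants(c(2, 5), c("SNP", "DEL"), c("T", ""), c(1, 2)))
#' g$loci
build_variation_graph <- function(reference, variants = NULL, lenient = FALSE) {
  ref <- as_reference_string(reference)
  if (is.null(variants)) {
    variants <- tibble(
      coordinate = integer(), vtype = character(),
      allele = character(), span = integer()
    )
  }
  v <- validate_variants(variants, ref, lenient = lenient)
  v <- arrange(v, .data$coordinate, .data$vtype, .data$allele, .data$span)

  if (nrow(v) == 0) {
    loci <- tibble(
      coordinate = integer(), n_variants = integer(),
      delta_ins = integer(), delta_del = integer(),
      has_snp = logical(), has_ins = logical(), has_del = logical(),
      penalty = integer()
    )
  } else {
    loci <- summarise(
      group_by(v, .data$coordinate),
      n_variants = dplyr::n(),
      delta_ins = max(c(0L, nchar(.data$allele[.data$vtype == "INS"]))),
      delta_del = max(c(0L, .data$span[.data$vtype == "DEL"])),
      has_snp = any(.data$vtype == "SNP"),
      has_ins = any(.data$vtype == "INS"),
      has_del = any(.data$vtype == "DEL"),
      .groups = "drop"
    )
    loci$penalty <- penalty_from_components(
      loci$delta_ins, loci$delta_del, loci$has_snp, loci$has_ins, loci$has_del
    )
  }

  structure(
    list(reference = ref, length = nchar(ref), variants = v, loci = loci),
    class = "variation_graph"
  )
}

as_reference_string <- function(reference) {
  if (inherits(reference, "DNAStringSet")) reference <- reference[[1]]
  if (inherits(reference, "XString")) reference <- as.character(reference)
  if (!is.character(reference) || length(reference) != 1) {
    abort("`reference` must be a single character string or a DNAString(Set)")
  }
  unname(toupper(reference))
}

#' @export
#' @method print variation_graph
print.variation_graph <- function(x, ...) {
  cat(sprintf(
    "<variation_graph> reference length %d, %d variant(s) at %d locus/loci\n",
    x$length, nrow(x$variants), nrow(x$loci)
  ))
  if (nrow(x$loci) > 0) print(x$loci, n = 5)
  invisible(x)
}

n_loci <- function(graph) nrow(graph$loci)
variant_coordinates <- function(graph) graph$loci$coordinate

#' Materialize the reduced graph implied by a selection
#'
#' Drops every variant at the removed coordinates; the outgoing label at a
#' removed locus falls back to the reference base. The reference axis is
#' unchanged.
#'
#' @param graph A [build_variation_graph()] object.
#' @param result A `variant_selection` object or an integer vector of removed
#'   coordinates.
#' @return A `variation_graph` containing only the retained loci.
#' @export
apply_selection <- function(graph, result) {
  stopifnot(inherits(graph, "variation_graph"))
  removed <- if (inherits(result, "variant_selection")) {
    result$removed_coordinates
  } else {
    as.integer(result)
  }
  unknown <- setdiff(removed, variant_coordinates(graph))
  if (length(unknown) > 0) {
    abort(paste0(
      "removed coordinate(s) not present in graph: ",
      paste(utils::head(unknown, 5), collapse = ", ")
    ))
  }
  keep <- !(graph$variants$coordinate %in% removed)
  build_variation_graph(graph$reference, graph$variants[keep, ])
}

#' Per-type variant and locus counts
#'
#' Summary table in the style used to describe variation-graph inputs:
#' variant and variant-containing-locus counts per variant class.
#'
#' @param graph A `variation_graph`.
#' @return A tibble with one row per variant type plus a `total` row.
#' @export
variant_stats <- function(graph) {
  stopifnot(inherits(graph, "variation_graph"))
  v <- graph$variants
  per_type <- summarise(
    group_by(v, .data$vtype),
    n_variants = dplyr::n(),
    n_loci = dplyr::n_distinct(.data$coordinate),
    .groups = "drop"
  )
  bind_rows(
    per_type,
    tibble(vtype = "total", n_variants = nrow(v), n_loci = n_loci(graph))
  )
}

new_selection_result <- function(graph, removed, algorithm, alpha, delta,
                                 flags = character()) {
  loci <- graph$loci
  removed <- sort(as.integer(removed))
  retained <- setdiff(loci$coordinate, removed)
  keep <- loci$coordinate %in% retained
  decisions <- tibble(
    coordinate = loci$coordinate,
    n_variants = loci$n_variants,
    penalty = loci$penalty,
    decision = ifelse(keep, "keep", "drop")
  )
  structure(
    list(
      removed_coordinates = removed,
      retained_coordinates = sort(retained),
      retained_variant_count = sum(loci$n_variants[keep]),
      retained_locus_count = sum(keep),
      removed_variant_count = sum(loci$n_variants[!keep]),
      removed_locus_count = sum(!keep),
      total_variant_count = sum(loci$n_variants),
      total_locus_count = nrow(loci),
      decisions = decisions,
      algorithm = algorithm,
      alpha = as.integer(alpha),
      delta = as.integer(delta),
      flags = flags
    ),
    class = "variant_selection"
  )
}

#' @export
#' @method print variant_selection
print.variant_selection <- function(x, ...) {
  pct <- function(a, b) if (b == 0) 0 else 100 * a / b
  cat(sprintf(
    "<variant_selection> %s (alpha = %d, delta = %d)\n", x$algorithm, x$alpha, x$delta
  ))
  cat(sprintf(
    "  loci:     %d removed / %d total (%.2f%%)\n",
    x$removed_locus_count, x$total_locus_count,
    pct(x$removed_locus_count, x$total_locus_count)
  ))
  cat(sprintf(
    "  variants: %d removed / %d total (%.2f%%)\n",
    x$removed_variant_count, x$total_variant_count,
    pct(x$removed_variant_count, x$total_variant_count)
  ))
  if (length(x$flags) > 0) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.variant_selection <- function(x, ...) x$decisions

#' @export
glance.variant_selection <- function(x, ...) {
  tibble(
    algorithm = x$algorithm, alpha = x$alpha, delta = x$delta,
    n_loci = x$total_locus_count, n_variants = x$total_variant_count,
    loci_removed = x$removed_locus_count, loci_retained = x$retained_locus_count,
    variants_removed = x$removed_variant_count,
    variants_retained = x$retained_variant_count,
    pct_loci_removed = ifelse(x$total_locus_count == 0, 0,
      100 * x$removed_locus_count / x$total_locus_count
    ),
    pct_variants_removed = ifelse(x$total_variant_count == 0, 0,
      100 * x$removed_variant_count / x$total_variant_count
    ),
    timed_out = "timeout" %in% x$flags
  )
}

#' @export
autoplot.variant_selection <- function(object, ...) {
  d <- object$decisions
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$coordinate, y = .data$n_variants,
    colour = .data$decision
  )) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$coordinate, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(keep = "#1b7837", drop = "#bdbdbd")) +
    ggplot2::labs(
      x = "reference coordinate", y = "variants at locus",
      title = sprintf(
        "%s: %d/%d loci removed (alpha = %d, delta = %d)",
        object$algorithm, object$removed_locus_count,
        object$total_locus_count, object$alpha, object$delta
      )
    ) +
    ggplot2::theme_minimal()
}
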