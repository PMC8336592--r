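#' Specification for a simulated variant catalogue
#'
#' Bundles and validates the parameters of [simulate_variation()]. The
#' defaults emulate the three catalogue regimes the selection algorithms are
#' aimed at, scaled from human chromosome-scale call sets: dense biallelic
#' SNPs with a mean inter-SNP gap of 39 bp, short indels (1-50 bp, roughly
#' one per kbp), and insertion/deletion structural variants of at least
#' 50 bp placed without mutual overlap.
#'
#' @param ref_length Reference length in bp.
#' @param snp_rate Per-base probability of a SNP locus. Default `1/39`.
#' @param p_multiallelic Probability that a SNP locus carries a second
#'   alternative allele (and, recursively, a third). Default `0.003`.
#' @param indel_rate Per-base probability of a short indel. Default `0.001`.
#' @param indel_len_p Geometric success parameter for short-indel lengths,
#'   truncated to `[1, 50]`. Default `0.35` (mean ~2.9 bp).
#' @param sv_count Number of structural variants to place.
#' @param sv_len_min,sv_len_max Structural-variant length range; lengths are
#'   drawn log-uniformly. Defaults 50 and 5000 bp.
#' @param sv_overlap Allow SV deletions to overlap each other. Default
#'   `FALSE`.
#' @param seed Integer seed; simulation is deterministic given the spec.
#' @return A validated list of class `sim_spec`.
#' @export
sim_spec <- function(ref_length, snp_rate = 1 / 39, p_multiallelic = 0.003,
                     indel_rate = 0.001, indel_len_p = 0.35,
                     sv_count = 0, sv_len_min = 50, sv_len_max = 5000,
                     sv_overlap = FALSE, seed = 1L) {
  spec <- list(
    ref_length = as.integer(ref_length), snp_rate = snp_rate,
    p_multiallelic = p_multiallelic, indel_rate = indel_rate,
    indel_len_p = indel_len_p, sv_count = as.integer(sv_count),
    sv_len_min = as.integer(sv_len_min), sv_len_max = as.integer(sv_len_max),
    sv_overlap = isTRUE(sv_overlap), seed = as.integer(seed)
  )
  rates <- c(spec$snp_rate, spec$p_multiallelic, spec$indel_rate, spec$indel_len_p)
  if (any(rates < 0 | rates > 1)) abort("all rates must lie in [0, 1]")
  if (spec$ref_length < 1) abort("`ref_length` must be >= 1")
  if (spec$sv_count < 0) abort("`sv_count` must be >= 0")
  if (spec$sv_len_min < 1 || spec$sv_len_max < spec$sv_len_min) {
    abort("require 1 <= sv_len_min <= sv_len_max")
  }
  if (spec$sv_count > 0 && spec$sv_len_min > spec$ref_length) {
    abort("structural variants cannot be longer than the reference")
  }
  structure(spec, class = "sim_spec")
}

other_bases <- function(base) {
  lapply(base, function(b) setdiff(c("A", "C", "G", "T"), b))
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a reference and a variant catalogue
#'
#' Draws a uniform random reference and seeds it with SNPs (alternative
#' alleles uniform over the three non-reference bases, optionally
#' multi-allelic), short indels with geometric lengths truncated to 50 bp,
#' and log-uniform-length structural variants placed without overlap (unless
#' allowed). Deterministic given `spec$seed`.
#'
#' @param spec A [sim_spec()].
#' @return A list with `reference` (character string), `variants` (tibble as
#'   for [build_variation_graph()]) and `counts` (per-type truth counts).
#' @export
#' @examples
#' sim <- simulate_variation(sim_spec(1000, snp_rate = 0.02, seed = 7))
#' nrow(sim$variants)
simulate_variation <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  withr::with_seed(spec$seed, simulate_variation_impl(spec))
}

simulate_variation_impl <- function(spec) {
  L <- spec$ref_length
  ref <- random_seq(L)
  ref_bases <- strsplit(ref, "", fixed = TRUE)[[1]]
  parts <- list()

  # SNPs (possibly multi-allelic)
  if (spec$snp_rate > 0) {
    at <- which(stats::runif(L) < spec$snp_rate) - 1L
    if (length(at) > 0) {
      alt_pool <- other_bases(ref_bases[at + 1L])
      first_alt <- vapply(alt_pool, function(x) sample(x, 1L), character(1))
      snp <- tibble(coordinate = at, vtype = "SNP", allele = first_alt, span = 1L)
      extra2 <- stats::runif(length(at)) < spec$p_multiallelic
      if (any(extra2)) {
        second <- vapply(
          which(extra2),
          function(i) sample(setdiff(alt_pool[[i]], first_alt[i]), 1L),
          character(1)
        )
        snp <- bind_rows(snp, tibble(
          coordinate = at[extra2], vtype = "SNP", allele = second, span = 1L
        ))
        extra3 <- which(extra2)[stats::runif(sum(extra2)) < spec$p_multiallelic]
        if (length(extra3) > 0) {
          third <- vapply(
            extra3,
            function(i) setdiff(alt_pool[[i]], c(first_alt[i], second[match(i, which(extra2))])),
            character(1)
          )
          snp <- bind_rows(snp, tibble(
            coordinate = at[extra3], vtype = "SNP", allele = third, span = 1L
          ))
        }
      }
      parts$snp <- snp
    }
  }

  # short indels, geometric length truncated to [1, 50]
  if (spec$indel_rate > 0) {
    at <- which(stats::runif(L) < spec$indel_rate) - 1L
    if (length(at) > 0) {
      len <- pmin(stats::rgeom(length(at), spec$indel_len_p) + 1L, 50L)
      is_ins <- stats::runif(length(at)) < 0.5
      del_ok <- !is_ins & (at + len <= L)
      ins <- tibble(
        coordinate = at[is_ins], vtype = "INS",
        allele = vapply(len[is_ins], random_seq, character(1)), span = 0L
      )
      del <- tibble(
        coordinate = at[del_ok], vtype = "DEL", allele = "", span = len[del_ok]
      )
      parts$indel <- bind_rows(ins, del)
    }
  }

  # structural variants, log-uniform lengths, non-overlapping placement
  if (spec$sv_count > 0) {
    len <- as.integer(round(exp(stats::runif(
      spec$sv_count, log(spec$sv_len_min), log(spec$sv_len_max)
    ))))
    len <- pmin(pmax(len, spec$sv_len_min), spec$sv_len_max)
    is_ins <- stats::runif(spec$sv_count) < 0.5
    occupied_start <- integer()
    occupied_end <- integer()
    coords <- integer(spec$sv_count)
    for (k in seq_len(spec$sv_count)) {
      extent <- if (is_ins[k]) 1L else len[k]
      max_start <- L - extent
      if (max_start < 0) abort("infeasible sim_spec: SV longer than reference")
      placed <- FALSE
      for (try in seq_len(1000L)) {
        c0 <- sample.int(max_start + 1L, 1L) - 1L
        if (spec$sv_overlap ||
          !any(c0 < occupied_end & (c0 + extent) > occupied_start)) {
          coords[k] <- c0
          occupied_start <- c(occupied_start, c0)
          occupied_end <- c(occupied_end, c0 + max(extent, 1L))
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort("infeasible sim_spec: could not place non-overlapping SVs; lower sv_count")
      }
    }
    parts$sv <- tibble(
      coordinate = coords,
      vtype = ifelse(is_ins, "INS", "DEL"),
      allele = ifelse(is_ins, vapply(len, random_seq, character(1)), ""),
      span = ifelse(is_ins, 0L, len)
    )
  }

  v <- if (length(parts) > 0) bind_rows(parts) else variants()
  # a degenerate clash is impossible for SNPs (alts exclude the reference
  # base), but identical tuples can arise across part draws
  v <- distinct(arrange(v, .data$coordinate, .data$vtype, .data$allele, .data$span))
  counts <- summarise(
    group_by(v, .data$vtype),
    n = dplyr::n(), .groups = "drop"
  )
  list(reference = ref, variants = v, counts = counts)
}
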