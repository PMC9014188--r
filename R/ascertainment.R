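#' GWAS ascertainment schemes
#'
#' Describes which causal loci enter the polygenic score, mimicking idealized
#' GWAS discovery in the represented population: every segregating locus
#' (`all`), the top fraction `q` of loci ranked by the genic variance they
#' contribute (`top_variance_fraction`, power-based discovery), or every
#' locus whose minor allele frequency exceeds `m` (`maf_threshold`).
#' Effects are always known exactly; discovery is the only filter.
#'
#' @param kind one of `"all"`, `"top_variance_fraction"`, `"maf_threshold"`.
#' @param q fraction of segregating loci kept under
#'   `top_variance_fraction` (default 0.05).
#' @param m MAF cutoff under `maf_threshold` (default 0.01).
#' @param source population whose frequencies define discovery: `"A"`, `"B"`
#'   or `"both"` (a locus qualifies if it qualifies in either population).
#' @return An object of class `ascertainment_scheme`.
#' @examples
#' ascertainment_scheme("top_variance_fraction", q = 0.05)
#' @export
ascertainment_scheme <- function(kind = c("all", "top_variance_fraction",
                                          "maf_threshold"),
                                 q = 0.05, m = 0.01, source = c("A", "B", "both")) {
  kind <- match.arg(kind)
  source <- match.arg(source)
  stopifnot(q > 0, q <= 1, m >= 0, m < 0.5)
  structure(list(kind = kind, q = q, m = m, source = source),
            class = "ascertainment_scheme")
}

#' Genic variance contributed by one locus
#' @param p allele frequency in `[0, 1]`.
#' @param a allele effect size.
#' @return `2 p (1 - p) a^2`.
#' @examples
#' per_locus_variance(0.5, 0.1)  # 0.005
#' @export
per_locus_variance <- function(p, a) {
  stopifnot(all(p >= 0), all(p <= 1))
  2 * p * (1 - p) * a^2
}

flag_one_source <- function(loci, scheme, pcol) {
  p <- loci[[pcol]]
  seg <- p > 0 & p < 1
  switch(scheme$kind,
    all = seg,
    maf_threshold = pmin(p, 1 - p) > scheme$m,
    top_variance_fraction = {
      v <- per_locus_variance(p, loci$effect)
      idx <- which(seg)
      keep <- rep(FALSE, nrow(loci))
      if (length(idx)) {
        k <- ceiling(scheme$q * length(idx))
        ord <- idx[order(-v[idx], loci$locus_id[idx])]
        keep[ord[seq_len(k)]] <- TRUE
      }
      keep
    })
}

#' Flag ascertained loci in a locus table
#'
#' Applies an [ascertainment_scheme()] to a [locus_table()], setting the
#' `ascertained` column deterministically from the table alone: ranking ties
#' under `top_variance_fraction` are broken by locus id. Loci private to the
#' unrepresented population are never ascertained when discovery uses the
#' represented population only, which is what erodes portability.
#'
#' @param loci a [locus_table()] data.frame.
#' @param scheme an [ascertainment_scheme()].
#' @return `loci` with its `ascertained` column replaced.
#' @export
ascertain <- function(loci, scheme) {
  stopifnot(inherits(scheme, "ascertainment_scheme"),
            all(c("effect", "p_A", "p_B", "locus_id") %in% names(loci)))
  flags <- switch(scheme$source,
    A = flag_one_source(loci, scheme, "p_A"),
    B = flag_one_source(loci, scheme, "p_B"),
    both = flag_one_source(loci, scheme, "p_A") |
           flag_one_source(loci, scheme, "p_B"))
  if (!any(flags))
    warning("no locus satisfies the ascertainment scheme; scores will have zero variance")
  loci$ascertained <- flags
  loci
}
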