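## Cytosine context classification and site-level methylation calling.
##
## Context is defined on the strand-local trinucleotide starting at the
## cytosine: C followed by G is CG; C, non-G, G is CHG; otherwise CHH
## (H = A, C or T).  On the minus strand the local sequence is the
## reverse complement of the plus-strand genome.

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Enumerate all cytosines of a genome with their sequence context
#'
#' Scans both strands: plus-strand cytosines are `C` in the reference,
#' minus-strand cytosines are `G` (a C on the reverse complement).
#' Sites whose context window contains `N` or runs off the chromosome
#' end are dropped; the number dropped is recorded in attribute
#' `"n_dropped"`.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @return `data.table` with `chrom`, `pos` (1-based), `strand`,
#'   `context`, ordered by chromosome and position.
#' @export
genome_cytosines <- function(genome) {
  out <- vector("list", length(genome))
  dropped <- 0L
  for (k in seq_along(genome)) {
    chrom <- names(genome)[k]
    s <- strsplit(as.character(genome[[k]]), "", fixed = TRUE)[[1]]
    n <- length(s)

    ## plus strand: C at i, next bases s[i+1], s[i+2]
    ip <- which(s == "C")
    n1 <- ifelse(ip + 1L <= n, s[pmin(ip + 1L, n)], NA_character_)
    n2 <- ifelse(ip + 2L <= n, s[pmin(ip + 2L, n)], NA_character_)
    ctx_p <- .context_from_next(n1, n2)

    ## minus strand: G at i; strand-local next bases are the
    ## complements of s[i-1], s[i-2]
    im <- which(s == "G")
    m1 <- ifelse(im - 1L >= 1L, .COMP[s[pmax(im - 1L, 1L)]], NA_character_)
    m2 <- ifelse(im - 2L >= 1L, .COMP[s[pmax(im - 2L, 1L)]], NA_character_)
    ctx_m <- .context_from_next(m1, m2)

    dropped <- dropped + sum(is.na(ctx_p)) + sum(is.na(ctx_m))
    dt <- data.table::data.table(
      chrom = chrom,
      pos = c(ip, im),
      strand = rep(c("+", "-"), c(length(ip), length(im))),
      context = c(ctx_p, ctx_m)
    )
    out[[k]] <- dt[!is.na(context)]
  }
  res <- data.table::rbindlist(out)
  data.table::setorder(res, chrom, pos, strand)
  data.table::setattr(res, "n_dropped", dropped)
  res[]
}

#' @keywords internal
#' @noRd
.context_from_next <- function(n1, n2) {
  h <- c("A", "C", "T")
  data.table::fcase(
    is.na(n1), NA_character_,
    n1 == "G", "CG",
    !(n1 %in% h), NA_character_,   # N in window
    is.na(n2), NA_character_,
    n2 == "G", "CHG",
    n2 %in% h, "CHH",
    default = NA_character_        # N at third position
  )
}

#' Classify the sequence context of specific cytosines
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param chrom,pos,strand Parallel vectors identifying cytosines
#'   (1-based positions; strand `+`/`-`).
#' @return Character vector of contexts (`CG`, `CHG`, `CHH`), `NA`
#'   where the context window contains `N` or is truncated.  Errors if
#'   a queried position is not a cytosine on the given strand.
#' @export
classify_context <- function(genome, chrom, pos, strand) {
  all_c <- genome_cytosines(genome)
  query <- data.table::data.table(chrom = as.character(chrom),
                                  pos = as.integer(pos),
                                  strand = as.character(strand))
  ## verify each query really is a cytosine on its strand
  for (i in seq_len(nrow(query))) {
    q <- query[i]
    if (!(q$chrom %in% names(genome))) {
      stop("unknown chromosome: ", q$chrom, call. = FALSE)
    }
    base <- as.character(Biostrings::subseq(genome[[q$chrom]],
                                            q$pos, q$pos))
    want <- if (q$strand == "+") "C" else "G"
    if (base != want) {
      stop("position ", q$chrom, ":", q$pos, " (", q$strand,
           ") is not a cytosine on that strand", call. = FALSE)
    }
  }
  res <- all_c[query, on = c("chrom", "pos", "strand")]
  res$context
}

#' Estimate the bisulfite non-conversion rate
#'
#' With a truly unmethylated control contig (e.g. a lambda spike-in),
#' the rate is the pooled fraction of methylated calls over the control:
#' `sum(n_meth) / sum(n_total)`; bisulfite conversion efficiency (BCE)
#' is its complement.  Without a control, the global CHH level is used
#' as a proxy (CHH methylation is near zero in most invertebrate
#' genomes), with a message noting the caveat.
#'
#' @param records Cytosine record `data.table` (from [read_cx_table()]
#'   or the simulator).
#' @param control_contig Name of the unmethylated control contig, or
#'   `NULL` to fall back to the CHH proxy.
#' @return List with `rate` (non-conversion rate) and `bce`
#'   (conversion efficiency, `1 - rate`).
#' @export
estimate_nonconversion <- function(records, control_contig = NULL) {
  if (!is.null(control_contig)) {
    ctl <- records[chrom == control_contig & n_total > 0]
    if (nrow(ctl) == 0L || sum(ctl$n_total) == 0) {
      stop("no covered sites on control contig '", control_contig, "'",
           call. = FALSE)
    }
    rate <- sum(ctl$n_meth) / sum(ctl$n_total)
  } else {
    chh <- records[context == "CHH" & n_total > 0]
    if (nrow(chh) == 0L) {
      stop("no covered CHH sites for the non-conversion proxy",
           call. = FALSE)
    }
    message("estimate_nonconversion: no control contig given; ",
            "using the global CHH level as a proxy (upper bound ",
            "when genuine CHH methylation is present)")
    rate <- sum(chh$n_meth) / sum(chh$n_total)
  }
  list(rate = rate, bce = 1 - rate)
}

#' Call methylated cytosines by binomial test against non-conversion
#'
#' Each covered site gets a one-sided binomial tail probability
#' `P(X >= n_meth | n_total, rate)` under the null that all apparent
#' methylation is bisulfite non-conversion, followed by
#' Benjamini-Hochberg correction across all tested sites.  Sites with
#' zero coverage are excluded from testing.
#'
#' @param records Cytosine record `data.table`.
#' @param nonconversion_rate Null methylation probability in `[0, 1)`.
#' @param alpha FDR threshold for calling a site methylated
#'   (default 0.05).
#' @return The tested records with added `p_value`, `q_value`,
#'   `is_methylated`.
#' @export
call_methylated_sites <- function(records, nonconversion_rate,
                                  alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 ||
      alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  if (nonconversion_rate < 0 || nonconversion_rate >= 1) {
    stop("nonconversion_rate must lie in [0, 1)", call. = FALSE)
  }
  tested <- records[n_total > 0]
  if (nrow(tested) == 0L) {
    stop("no covered sites to test", call. = FALSE)
  }
  tested <- data.table::copy(tested)
  tested[, p_value := pbinom(n_meth - 1L, n_total, nonconversion_rate,
                             lower.tail = FALSE)]
  tested[, q_value := p.adjust(p_value, method = "BH")]
  tested[, is_methylated := q_value <= alpha]
  tested[]
}

#' Global and per-context methylome summary
#'
#' Levels are read-count weighted by default
#' (`sum(n_meth) / sum(n_total)` within each context and overall); the
#' unweighted site-mean is available for sensitivity analysis.  When a
#' non-conversion rate is supplied, levels are corrected for false
#' methylation signal as `(m - r) / (1 - r)`, floored at 0.
#'
#' @param records Cytosine record `data.table`.
#' @param nonconversion_rate Rate used for level correction (default 0,
#'   i.e. no correction).
#' @param weighted Read-count weighting (default) versus site-mean.
#' @return List with `level_overall`, `level_by_context` (named CG/CHG/
#'   CHH), `n_sites_by_context`, `n_sites_total`.
#' @export
summarize_methylome <- function(records, nonconversion_rate = 0,
                                weighted = TRUE) {
  cov <- records[n_total > 0]
  if (nrow(cov) == 0L) {
    stop("no covered sites to summarise", call. = FALSE)
  }
  correct <- function(m) {
    pmax(0, (m - nonconversion_rate) / (1 - nonconversion_rate))
  }
  if (weighted) {
    by_ctx <- cov[, .(level = sum(n_meth) / sum(n_total), n = .N),
                  by = context]
    overall <- sum(cov$n_meth) / sum(cov$n_total)
  } else {
    by_ctx <- cov[, .(level = mean(n_meth / n_total), n = .N),
                  by = context]
    overall <- mean(cov$n_meth / cov$n_total)
  }
  ctxs <- c("CG", "CHG", "CHH")
  lv <- setNames(rep(NA_real_, 3L), ctxs)
  ns <- setNames(rep(0L, 3L), ctxs)
  lv[by_ctx$context] <- correct(by_ctx$level)
  ns[by_ctx$context] <- by_ctx$n
  list(level_overall = correct(overall),
       level_by_context = lv,
       n_sites_by_context = ns,
       n_sites_total = nrow(cov))
}
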