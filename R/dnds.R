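# Nei-Gojobori (1986) dN/dS: equal-weight pathway counting of
# synonymous and nonsynonymous sites and differences with Jukes-Cantor
# correction. This is a desk-scale selection metric: codon-model methods
# (maximum-likelihood dN/dS, per-site likelihood tests) are deliberately
# out of scope, and all outputs are labelled as Nei-Gojobori counts.

NUCS <- c("A", "C", "G", "T")

genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- gsub("U", "T", names(gc))
  gc
}

is_stop <- function(codon, code = genetic_code()) code[[codon]] == "*"

split_codons <- function(seq) {
  seq <- toupper(gsub("\\s", "", seq))
  if (nchar(seq) %% 3L != 0L)
    stop("sequence length ", nchar(seq), " not divisible by 3")
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

codon_ok <- function(codon) {
  all(strsplit(codon, "")[[1]] %in% NUCS)
}

# fraction of synonymous single-nucleotide neighbours, per position.
# Changes to stop codons count as nonsynonymous sites.
codon_sites <- function(codon, code = genetic_code()) {
  aa <- code[[codon]]
  chars <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) for (nt in setdiff(NUCS, chars[pos])) {
    mut <- chars; mut[pos] <- nt
    if (code[[paste(mut, collapse = "")]] == aa) s <- s + 1 / 3
  }
  c(S = s, N = 3 - s)
}

# synonymous/nonsynonymous differences between two codons, averaged with
# equal weight over all orderings of the single-nucleotide steps;
# pathways passing through a stop codon are excluded (unless every
# pathway does, in which case all are used).
codon_differences <- function(a, b, code = genetic_code()) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  diff_pos <- which(ca != cb)
  nd <- length(diff_pos)
  if (nd == 0L) return(c(Sd = 0, Nd = 0))
  perms <- switch(nd,
    `1` = list(diff_pos),
    `2` = list(diff_pos, rev(diff_pos)),
    `3` = {
      p <- diff_pos
      list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
           p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
    })
  walk <- function(order) {
    cur <- ca; s <- 0; n <- 0; blocked <- FALSE
    for (pos in order) {
      aa_from <- code[[paste(cur, collapse = "")]]
      cur[pos] <- cb[pos]
      nxt <- paste(cur, collapse = "")
      aa_to <- code[[nxt]]
      if (aa_to == "*" && nxt != b) blocked <- TRUE
      if (aa_from == aa_to) s <- s + 1 else n <- n + 1
    }
    list(s = s, n = n, blocked = blocked)
  }
  paths <- lapply(perms, walk)
  ok <- !vapply(paths, `[[`, logical(1), "blocked")
  if (!any(ok)) ok <- rep(TRUE, length(paths))
  s <- mean(vapply(paths[ok], `[[`, numeric(1), "s"))
  n <- mean(vapply(paths[ok], `[[`, numeric(1), "n"))
  c(Sd = s, Nd = n)
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(Inf)
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise Nei-Gojobori dN/dS
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per codon (each
#' position contributes its fraction of synonymous single-nucleotide
#' changes, averaged over the two sequences) and synonymous/
#' nonsynonymous differences (multi-difference codons averaged with
#' equal weight over all mutational pathway orderings, stop-passing
#' pathways excluded). Proportions are Jukes-Cantor corrected:
#' `d = -(3/4) ln(1 - (4/3) p)`. Codons containing gaps or ambiguous
#' bases in either sequence are skipped pairwise.
#'
#' @param seq_a,seq_b in-frame nucleotide strings of equal length
#' @param code named genetic-code vector (default: the standard code)
#' @return object of class `selection_result`: list with `codons_used`,
#'   `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `dS`, `dN`, `omega`,
#'   `omega_defined`
#' @export
ng86_pairwise <- function(seq_a, seq_b, code = genetic_code()) {
  ca <- split_codons(seq_a); cb <- split_codons(seq_b)
  if (length(ca) != length(cb))
    stop("sequences differ in codon count (", length(ca), " vs ",
         length(cb), ")")
  S <- N <- Sd <- Nd <- 0
  used <- 0L
  for (k in seq_along(ca)) {
    a <- ca[k]; b <- cb[k]
    if (!codon_ok(a) || !codon_ok(b)) next   # pairwise deletion
    if (is_stop(a, code))
      stop("stop codon in sequence a at codon ", k)
    if (is_stop(b, code))
      stop("stop codon in sequence b at codon ", k)
    sa <- codon_sites(a, code); sb <- codon_sites(b, code)
    S <- S + (sa["S"] + sb["S"]) / 2
    N <- N + (sa["N"] + sb["N"]) / 2
    d <- codon_differences(a, b, code)
    Sd <- Sd + d["Sd"]; Nd <- Nd + d["Nd"]
    used <- used + 1L
  }
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  dS <- jc_correct(unname(pS)); dN <- jc_correct(unname(pN))
  defined <- !is.na(dS) && !is.na(dN) && is.finite(dS) && dS > 0
  structure(list(codons_used = used,
                 S = unname(S), N = unname(N),
                 Sd = unname(Sd), Nd = unname(Nd),
                 pS = unname(pS), pN = unname(pN),
                 dS = unname(dS), dN = unname(dN),
                 omega = if (defined) unname(dN / dS) else NA_real_,
                 omega_defined = defined),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(paste0("Nei-Gojobori: %d codons, Sd=%.2f/S=%.2f, ",
                     "Nd=%.2f/N=%.2f, dS=%.4f, dN=%.4f, omega=%s\n"),
              x$codons_used, x$Sd, x$S, x$Nd, x$N, x$dS, x$dN,
              if (x$omega_defined) sprintf("%.4f", x$omega)
              else "undefined"))
  invisible(x)
}

#' Per-codon selection summary over a codon alignment
#'
#' For every codon column, pools synonymous/nonsynonymous site and
#' difference counts (Nei-Gojobori) over all sequence pairs. No
#' Jukes-Cantor correction is applied at single-codon scale; the
#' proportions `pN/pS` are reported together with a conservation flag
#' for codons without any observed substitution.
#'
#' @param codon_msa an `msa` whose rows are in-frame nucleotide
#'   sequences (length divisible by 3), or a character vector of
#'   sequences
#' @param code genetic code
#' @return data.frame of class `per_codon_selection`: columns `codon`,
#'   `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `omega_prop` (ratio of
#'   proportions, `NA` when undefined) and `conserved`
#' @export
per_codon_selection <- function(codon_msa, code = genetic_code()) {
  seqs <- if (inherits(codon_msa, "msa"))
    apply(codon_msa$seqs, 1, paste, collapse = "") else codon_msa
  codons <- lapply(seqs, split_codons)
  ncod <- unique(lengths(codons))
  if (length(ncod) != 1L) stop("sequences differ in codon count")
  nseq <- length(codons)
  if (nseq < 2L) stop("need at least 2 sequences")
  out <- data.frame(codon = seq_len(ncod), S = 0, N = 0, Sd = 0, Nd = 0)
  site_cache <- new.env(parent = emptyenv())
  get_sites <- function(cd) {
    if (is.null(site_cache[[cd]])) site_cache[[cd]] <- codon_sites(cd, code)
    site_cache[[cd]]
  }
  for (k in seq_len(ncod)) {
    for (i in seq_len(nseq - 1L)) for (j in (i + 1L):nseq) {
      a <- codons[[i]][k]; b <- codons[[j]][k]
      if (!codon_ok(a) || !codon_ok(b)) next
      if (is_stop(a, code) || is_stop(b, code))
        stop("stop codon at codon ", k, " violates the reading frame")
      sa <- get_sites(a); sb <- get_sites(b)
      out$S[k] <- out$S[k] + (sa[["S"]] + sb[["S"]]) / 2
      out$N[k] <- out$N[k] + (sa[["N"]] + sb[["N"]]) / 2
      d <- codon_differences(a, b, code)
      out$Sd[k] <- out$Sd[k] + d[["Sd"]]
      out$Nd[k] <- out$Nd[k] + d[["Nd"]]
    }
  }
  out$pS <- ifelse(out$S > 0, out$Sd / out$S, NA_real_)
  out$pN <- ifelse(out$N > 0, out$Nd / out$N, NA_real_)
  out$omega_prop <- ifelse(!is.na(out$pS) & out$pS > 0,
                           out$pN / out$pS, NA_real_)
  out$conserved <- (out$Sd + out$Nd) == 0
  class(out) <- c("per_codon_selection", "data.frame")
  out
}

#' Pooled dN/dS estimate for a codon alignment
#'
#' Sums Nei-Gojobori sites and differences over all sequence pairs and
#' all codons, then applies the Jukes-Cantor correction to the pooled
#' proportions.
#'
#' @inheritParams per_codon_selection
#' @return a `selection_result` (see [ng86_pairwise()])
#' @export
estimate_omega <- function(codon_msa, code = genetic_code()) {
  seqs <- if (inherits(codon_msa, "msa"))
    apply(codon_msa$seqs, 1, paste, collapse = "") else codon_msa
  nseq <- length(seqs)
  if (nseq < 2L) stop("need at least 2 sequences")
  S <- N <- Sd <- Nd <- 0; used <- 0L
  for (i in seq_len(nseq - 1L)) for (j in (i + 1L):nseq) {
    r <- ng86_pairwise(seqs[[i]], seqs[[j]], code)
    S <- S + r$S; N <- N + r$N; Sd <- Sd + r$Sd; Nd <- Nd + r$Nd
    used <- used + r$codons_used
  }
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  dS <- jc_correct(pS); dN <- jc_correct(pN)
  defined <- !is.na(dS) && !is.na(dN) && is.finite(dS) && dS > 0
  structure(list(codons_used = used, S = S, N = N, Sd = Sd, Nd = Nd,
                 pS = pS, pN = pN, dS = dS, dN = dN,
                 omega = if (defined) dN / dS else NA_real_,
                 omega_defined = defined),
            class = "selection_result")
}
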