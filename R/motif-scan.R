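# PWM construction, JASPAR I/O, promoter extraction, log-odds scanning on
# both strands, and tail p-values for window scores by dynamic programming.

DNA_BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix
#'
#' Normalizes a 4 x w count (or frequency) matrix column-wise with a
#' background-split pseudocount: `freq = (count + pseudocount * background) /
#' (colsum + pseudocount)`. Columns therefore sum to 1 exactly. A pseudocount
#' of 0 is permitted for closed-form work but scanning requires a strictly
#' positive pseudocount so every log-odds score is finite.
#'
#' @param counts Numeric 4 x w matrix; rows A, C, G, T (rownames optional but
#'   checked when present).
#' @param name Motif name.
#' @param pseudocount Non-negative pseudocount, split by background
#'   (default 0.8).
#' @param background Base probabilities (A, C, G, T) summing to 1; default
#'   uniform.
#' @return An object of class `triadnet_pwm` with elements `freq`, `counts`,
#'   `name`, `pseudocount`, `background`, `width`.
#' @export
pwm <- function(counts, name = "motif", pseudocount = 0.8,
                background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L || ncol(counts) < 1L) {
    abort("`counts` must be a 4 x w matrix (rows A, C, G, T), w >= 1.")
  }
  if (!is.null(rownames(counts)) &&
      !identical(toupper(rownames(counts)), DNA_BASES)) {
    abort("Rownames, when present, must be A, C, G, T in order.")
  }
  if (any(counts < 0) || pseudocount < 0) {
    abort("Counts and pseudocount must be non-negative.")
  }
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-9 ||
      any(background <= 0)) {
    abort("`background` must be 4 positive probabilities summing to 1.")
  }
  background <- setNames(as.numeric(background), DNA_BASES)
  rownames(counts) <- DNA_BASES
  csum <- colSums(counts)
  if (any(csum == 0)) abort("Every PWM column needs positive total count.")
  freq <- sweep(counts + pseudocount * background, 2L, csum + pseudocount, "/")
  structure(list(freq = freq, counts = counts, name = name,
                 pseudocount = pseudocount, background = background,
                 width = ncol(counts)),
            class = "triadnet_pwm")
}

#' @export
print.triadnet_pwm <- function(x, ...) {
  cat(sprintf("<PWM %s> width %d, pseudocount %g\n", x$name, x$width,
              x$pseudocount))
  print(round(x$freq, 3))
  invisible(x)
}

#' Log-odds score matrix of a PWM
#'
#' Entry `(b, j)` is `log2(freq[b, j] / background[b])`. With pseudocount 0 a
#' zero frequency yields `-Inf`; such matrices are valid for closed-form
#' arithmetic but rejected by [scan_sequences()].
#'
#' @param x A [pwm()] object.
#' @return 4 x w numeric matrix, rows A, C, G, T.
#' @export
log_odds_matrix <- function(x) {
  stopifnot(inherits(x, "triadnet_pwm"))
  log2(x$freq / x$background)
}

# Distribution of the log-odds score of a random background window.
# method "exact": hash-based DP over achievable partial sums (feasible for
#   4^w up to ~1e6, i.e. w <= 10); exact to float rounding (keys merged at
#   1e-9 resolution).
# method "lattice": DP over integer-rescaled scores with the documented bin
#   width; -Inf entries contribute zero mass to any finite tail.
# Returns list(score = sorted support, prob, slack) where `slack` is the
# score-space tolerance to use when reading a tail probability.
score_distribution <- function(lom, background, method = "auto", bin = 1e-3) {
  w <- ncol(lom)
  method <- match.arg(method, c("auto", "exact", "lattice"))
  if (method == "auto") method <- if (w <= 10L) "exact" else "lattice"
  if (method == "exact") {
    score <- 0
    prob <- 1
    for (j in seq_len(w)) {
      s_new <- as.vector(outer(score, lom[, j], "+"))
      p_new <- as.vector(outer(prob, background, "*"))
      key <- round(s_new, 9L)
      agg <- rowsum(p_new, group = key)
      score <- as.numeric(rownames(agg))
      prob <- as.vector(agg)
    }
    o <- order(score)
    return(list(score = score[o], prob = prob[o], slack = 1e-9))
  }
  finite <- is.finite(lom)
  if (any(colSums(finite) == 0L)) {
    abort("Lattice DP needs at least one finite score per column.")
  }
  k <- round(lom / bin)
  k[!finite] <- NA_integer_
  cur <- c(1)
  cur_min <- 0L
  for (j in seq_len(w)) {
    nxt_min <- cur_min + min(k[, j], na.rm = TRUE)
    nxt_len <- length(cur) + (max(k[, j], na.rm = TRUE) -
                                min(k[, j], na.rm = TRUE))
    nxt <- numeric(nxt_len)
    for (b in which(finite[, j])) {
      off <- k[b, j] - min(k[, j], na.rm = TRUE)
      idx <- seq_along(cur) + off
      nxt[idx] <- nxt[idx] + cur * background[b]
    }
    cur <- nxt
    cur_min <- nxt_min
  }
  list(score = (cur_min + seq_along(cur) - 1L) * bin, prob = cur,
       slack = w * bin / 2 + 1e-12)
}

#' Tail p-value of a PWM window score
#'
#' Probability that a random background window scores at least `s` under the
#' log-odds matrix. Computed by dynamic programming over the score
#' distribution: exactly over the achievable score set for motifs of width up
#' to 10, and over an integer-rescaled lattice (bin width `bin` on the
#' log-odds scale, default `1e-3`) for wider motifs, where the answer is exact
#' for integer-rescaled matrices and conservative within half a bin per
#' column otherwise. A score above the attainable maximum returns exactly 0.
#'
#' @param x A [pwm()] object or a 4 x w log-odds matrix.
#' @param s Query score (may be a vector).
#' @param background Base probabilities; taken from the PWM when omitted.
#' @param method `"auto"` (default), `"exact"` or `"lattice"`.
#' @param bin Lattice bin width on the log-odds scale.
#' @return Numeric vector of tail probabilities in `[0, 1]`.
#' @export
score_pvalue <- function(x, s, background = NULL, method = "auto",
                         bin = 1e-3) {
  if (inherits(x, "triadnet_pwm")) {
    background <- background %||% x$background
    lom <- log_odds_matrix(x)
  } else {
    lom <- as.matrix(x)
    background <- background %||% rep(0.25, 4)
  }
  d <- score_distribution(lom, background, method = method, bin = bin)
  tail_p <- rev(cumsum(rev(d$prob)))
  vapply(s, function(si) {
    i <- findInterval(si - d$slack, d$score, left.open = TRUE) + 1L
    if (i > length(d$score)) 0 else tail_p[i]
  }, numeric(1))
}

# Integer codes (1..4) for a DNA string; ambiguous bases become NA.
encode_dna <- function(seq) {
  match(strsplit(toupper(as.character(seq)), "")[[1]], DNA_BASES)
}

revcomp_chr <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Window scores of one encoded sequence under a log-odds matrix; windows
# containing ambiguous bases score NA.
window_scores <- function(codes, lom) {
  w <- ncol(lom)
  L <- length(codes)
  if (L < w) return(numeric(0))
  sc <- numeric(L - w + 1L)
  for (j in seq_len(w)) {
    sc <- sc + lom[cbind(codes[j:(L - w + j)], j)]
  }
  sc
}

#' Scan sequences with a PWM on both strands
#'
#' Scores every window of width `w` on the forward and reverse strand with
#' the log-odds matrix, attaches the dynamic-programming tail p-value of each
#' score, and retains hits with `p_value < threshold_p` (strict). Coordinates
#' are 0-based half-open on the forward strand; a reverse-strand hit at
#' `[start, start + w)` means the motif matches the reverse complement of
#' that interval. Windows containing ambiguous bases are skipped.
#'
#' @param sequences Named character vector or [Biostrings::DNAStringSet].
#' @param x A [pwm()] object (pseudocount must be > 0 so scores are finite).
#' @param threshold_p Retention threshold on the tail p-value (default
#'   `1e-5`).
#' @param method,bin Passed to the p-value DP (see [score_pvalue()]).
#' @return Tibble with columns `seq_id`, `start`, `end`, `strand`, `score`,
#'   `p_value`, `tf`, sorted by sequence then position.
#' @export
scan_sequences <- function(sequences, x, threshold_p = 1e-5,
                           method = "auto", bin = 1e-3) {
  stopifnot(inherits(x, "triadnet_pwm"))
  if (x$pseudocount <= 0) {
    abort("Scanning requires pseudocount > 0 (finite log-odds scores).")
  }
  seqs <- as.character(sequences)
  ids <- names(sequences) %||% sprintf("seq_%d", seq_along(seqs))
  ids <- sub("\\s.*$", "", ids)
  lom <- log_odds_matrix(x)
  w <- x$width
  d <- score_distribution(lom, x$background, method = method, bin = bin)
  tail_p <- rev(cumsum(rev(d$prob)))
  p_of <- function(sc) {
    i <- findInterval(sc - d$slack, d$score, left.open = TRUE) + 1L
    ifelse(i > length(d$score), 0, tail_p[pmin(i, length(tail_p))])
  }
  res <- purrr::map2_dfr(seqs, ids, function(sq, id) {
    L <- nchar(sq)
    if (L < w) return(tibble())
    fwd <- window_scores(encode_dna(sq), lom)
    rev_ <- window_scores(encode_dna(revcomp_chr(sq)), lom)
    hits <- bind_rows(
      tibble(start = seq_along(fwd) - 1L, strand = "+", score = fwd),
      tibble(start = L - w - (seq_along(rev_) - 1L), strand = "-",
             score = rev_))
    hits <- hits[!is.na(hits$score), , drop = FALSE]
    if (nrow(hits) == 0L) return(tibble())
    hits$p_value <- p_of(hits$score)
    hits <- hits[hits$p_value < threshold_p, , drop = FALSE]
    if (nrow(hits) == 0L) return(tibble())
    mutate(hits, seq_id = id, end = .data$start + w, tf = x$name)
  })
  if (nrow(res) == 0L) {
    return(tibble(seq_id = character(), start = integer(), end = integer(),
                  strand = character(), score = double(), p_value = double(),
                  tf = character()))
  }
  res |>
    select("seq_id", "start", "end", "strand", "score", "p_value", "tf") |>
    arrange(.data$seq_id, .data$start, .data$strand)
}

#' Extract promoter windows around transcription start sites
#'
#' For a plus-strand gene the promoter is `[TSS - upstream, TSS + downstream)`
#' on the forward strand; for a minus-strand gene it is the reverse complement
#' of `[TSS - downstream, TSS + upstream)`, so the returned sequence always
#' reads 5'->3' on the coding strand. Coordinates are 0-based half-open.
#' Windows clipped at contig ends are truncated and flagged; a TSS outside
#' the contig is an error.
#'
#' @param tss_table Tibble with columns `gene`, `chrom`, `tss` (0-based),
#'   `strand` (`"+"` or `"-"`).
#' @param genome Named character vector or [Biostrings::DNAStringSet] of
#'   contigs.
#' @param upstream,downstream Window extents (defaults 1000 and 200, the
#'   standard promoter window used throughout the package).
#' @return Tibble `gene`, `chrom`, `tss`, `strand`, `sequence`, `truncated`.
#' @export
extract_promoters <- function(tss_table, genome, upstream = 1000L,
                              downstream = 200L) {
  stopifnot(all(c("gene", "chrom", "tss", "strand") %in% names(tss_table)))
  contigs <- as.character(genome)
  names(contigs) <- sub("\\s.*$", "", names(genome))
  purrr::pmap_dfr(tss_table, function(gene, chrom, tss, strand, ...) {
    if (!chrom %in% names(contigs)) abort(paste0("Unknown contig: ", chrom))
    L <- nchar(contigs[[chrom]])
    if (tss < 0 || tss >= L) {
      abort(sprintf("TSS %d outside contig %s (length %d).", tss, chrom, L))
    }
    if (strand == "+") {
      from <- tss - upstream
      to <- tss + downstream       # [from, to)
    } else {
      from <- tss - downstream
      to <- tss + upstream
    }
    truncated <- from < 0 || to > L
    from_c <- max(from, 0L)
    to_c <- min(to, L)
    s <- substr(contigs[[chrom]], from_c + 1L, to_c)
    if (strand == "-") s <- revcomp_chr(s)
    tibble(gene = gene, chrom = chrom, tss = tss, strand = strand,
           sequence = s, truncated = truncated)
  })
}

#' Call TF -> gene edges from retained motif hits
#'
#' One edge per (TF, gene) with at least one retained hit in the gene's
#' promoter; multiple hits are deduplicated and the edge carries the best
#' (lowest) hit p-value as evidence. Idempotent and order-independent.
#'
#' @param hits Hit tibble from [scan_sequences()] (possibly concatenated over
#'   PWMs).
#' @param gene_map Tibble mapping `seq_id` to `gene` (optionally with a
#'   `target_class` column; default `"gene"`).
#' @return Regulatory-edge tibble: `regulator`, `regulator_class`, `target`,
#'   `target_class`, `evidence` (best hit p-value).
#' @export
call_tf_gene_edges <- function(hits, gene_map) {
  stopifnot(all(c("seq_id", "tf", "p_value") %in% names(hits)),
            all(c("seq_id", "gene") %in% names(gene_map)))
  if (nrow(hits) == 0L) {
    return(tibble(regulator = character(), regulator_class = character(),
                  target = character(), target_class = character(),
                  evidence = double()))
  }
  if (!"target_class" %in% names(gene_map)) gene_map$target_class <- "gene"
  hits |>
    inner_join(gene_map, by = "seq_id", relationship = "many-to-many") |>
    group_by(regulator = .data$tf, target = .data$gene,
             target_class = .data$target_class) |>
    summarise(evidence = min(.data$p_value), .groups = "drop") |>
    mutate(regulator_class = "TF") |>
    select("regulator", "regulator_class", "target", "target_class",
           "evidence") |>
    arrange(.data$regulator, .data$target)
}

# ---- JASPAR + FASTA I/O -----------------------------------------------------

#' Read and write JASPAR-format PFM files
#'
#' The JASPAR text layout: a `>identifier name` header line, then four lines
#' `A [ 4 19 0 ... ]` (brackets optional) for A, C, G, T.
#'
#' @param path File path.
#' @param pseudocount,background Passed to [pwm()] on read.
#' @return `read_jaspar_pfm()`: a list of [pwm()] objects (length >= 1).
#' @export
read_jaspar_pfm <- function(path, pseudocount = 0.8,
                            background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0L) abort("No JASPAR records ('>' headers) found.")
  purrr::map(starts, function(i) {
    name <- trimws(sub("^>\\s*", "", lines[i]))
    block <- lines[(i + 1L):(i + 4L)]
    rows <- purrr::map(block, function(ln) {
      ln <- gsub("^[ACGTacgt]\\s*", "", trimws(ln))
      ln <- gsub("[", " ", ln, fixed = TRUE)
      ln <- gsub("]", " ", ln, fixed = TRUE)
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    })
    counts <- do.call(rbind, rows)
    pwm(counts, name = name, pseudocount = pseudocount,
        background = background)
  })
}

#' @rdname read_jaspar_pfm
#' @param x A [pwm()] object.
#' @export
write_jaspar_pfm <- function(x, path) {
  stopifnot(inherits(x, "triadnet_pwm"))
  fmt <- function(v) paste(format(v, trim = TRUE), collapse = " ")
  lines <- c(paste0(">", x$name),
             sprintf("%s [ %s ]", DNA_BASES,
                     vapply(seq_len(4), function(b) fmt(x$counts[b, ]),
                            character(1))))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname read_jaspar_pfm
#' @param sequences Named character vector or [Biostrings::DNAStringSet].
#' @export
write_fasta <- function(sequences, path) {
  if (!methods::is(sequences, "XStringSet")) {
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  Biostrings::writeXStringSet(sequences, path)
  invisible(path)
}

#' @rdname read_jaspar_pfm
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' @rdname read_jaspar_pfm
#' @param hits Hit tibble from [scan_sequences()].
#' @export
write_hits_tsv <- function(hits, path) readr::write_tsv(hits, path)
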