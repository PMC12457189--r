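#' Peptide sequence design spaces
#'
#' Candidates are length-`L` integer sequences over the 20-letter canonical
#' amino-acid alphabet (codes 0-19, mapped alphabetically to one-letter
#' symbols). Optional fixed (hotspot) positions are never mutated by the
#' expansion moves.
#'
#' @param L Sequence length (7-14 is typical for cyclic peptide binders;
#'   any `L >= 2` is accepted).
#' @param fixed Integer positions (1-based) excluded from mutation.
#' @return A `dante_space` whose dimensions are 20-letter alphabets.
#' @export
sequence_space <- function(L, fixed = integer(0)) {
  stopifnot(L >= 2, all(fixed >= 1), all(fixed <= L))
  if (length(fixed) >= L) stop("all positions fixed: degenerate space", call. = FALSE)
  sp <- categorical_space(L, 20)
  sp$kind <- "sequence"
  sp$fixed <- as.integer(sort(unique(fixed)))
  sp
}

# alphabetically ordered canonical amino acids; code 0 = A, ..., 19 = Y
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Integer codes to amino-acid strings and back
#'
#' The bijection between codes `0..19` and the alphabetically ordered
#' one-letter amino-acid symbols.
#'
#' @param codes Integer vector or matrix (rows = sequences) of codes 0-19.
#' @param seqs Character vector of amino-acid strings.
#' @return `codes_to_aa()` returns a character vector of sequences;
#'   `aa_to_codes()` returns an integer matrix of codes.
#' @export
codes_to_aa <- function(codes) {
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = 1)
  if (any(codes < 0 | codes > 19)) stop("codes must be in 0..19", call. = FALSE)
  apply(codes, 1, function(r) paste(AA_ALPHABET[r + 1], collapse = ""))
}

#' @rdname codes_to_aa
#' @export
aa_to_codes <- function(seqs) {
  rows <- lapply(strsplit(toupper(seqs), ""), function(ch) {
    m <- match(ch, AA_ALPHABET)
    if (anyNA(m)) stop("non-canonical amino acid letter", call. = FALSE)
    m - 1L
  })
  if (length(unique(lengths(rows))) != 1) {
    stop("sequences must share one length", call. = FALSE)
  }
  do.call(rbind, rows)
}

#' Stochastic expansion for sequence spaces
#'
#' Generates `L` leaves from a root sequence using the two complementary
#' strategies of the sequence-design search: point mutation of 1..`max_mut`
#' free positions, or an entirely fresh random sequence (probability
#' `p_fresh`). Fixed positions are never changed. Draws from the current R
#' RNG stream.
#'
#' @param root A single sequence candidate (codes, vector or one-row data
#'   frame).
#' @param space A [sequence_space()].
#' @param config An [nte_config()] (fields `p_fresh`, `max_mut`, `retry`).
#' @return Tibble of `L` leaves, each a valid sequence different from the
#'   root.
#' @export
sequence_expand <- function(root, space, config = nte_config(expand = "sequence")) {
  stopifnot(is_dante_space(space))
  x <- as.integer(cand_matrix(space, root)[1, ])
  free <- setdiff(seq_len(space$d), space$fixed)
  if (length(free) == 0) stop("all positions fixed: degenerate space", call. = FALSE)
  leaves <- matrix(NA_integer_, 0, space$d)
  for (j in seq_len(space$d)) {
    for (attempt in seq_len(config$retry)) {
      leaf <- x
      if (stats::runif(1) < config$p_fresh) {
        leaf[free] <- sample(0:19, length(free), replace = TRUE)
      } else {
        m <- sample(seq_len(max(config$max_mut, 1)), 1)
        pos <- sample(free, min(m, length(free)))
        for (p in pos) leaf[p] <- sample(setdiff(0:19, leaf[p]), 1)
      }
      if (!identical(leaf, x)) break
    }
    if (!identical(leaf, x)) leaves <- rbind(leaves, leaf)
  }
  out <- tibble::as_tibble(as.data.frame(leaves))
  names(out) <- paste0("x", seq_len(space$d))
  out
}

#' Synthetic binder-fitness oracle
#'
#' A deterministic, seeded stand-in for a structure-based scoring pipeline,
#' shaped like the peptide-binder design target: a bounded
#' shape-complementarity-like factor `sc` in \[0, 1\] multiplied by a
#' positive interface-size factor `dsasa` (solvent-accessible surface area
#' change, in square-Angstrom semantics), combined as
#' `target = sc * dsasa / 100`. The landscape is built from a hidden target
#' sequence with per-position match weights plus sparse pairwise epistasis
#' (`2 L` random position pairs with Gaussian weights), which creates local
#' optima; the global maximum is attained exactly at the hidden sequence.
#' The oracle is synthetic: it emulates the shape and difficulty of a
#' binder-design landscape, not any physical complex.
#'
#' @param L Sequence length.
#' @param seed Seed of the hidden landscape.
#' @param epistasis_pairs Number of random epistatic position pairs
#'   (default `2 * L`).
#' @param sc_gain Logistic gain of the complementarity factor.
#' @param dsasa_base,dsasa_spread Interface-size factor: `base + spread *`
#'   (weighted fraction of matched positions).
#' @return A `dante_objective` (direction `"maximize"`) with extra fields:
#'   `hidden` (the optimal code vector), `score_components(X)` returning a
#'   tibble with `sc`, `dsasa` and `target` columns.
#' @export
synthetic_binder_oracle <- function(L, seed = 1, epistasis_pairs = 2 * L,
                                    sc_gain = 4, dsasa_base = 300,
                                    dsasa_spread = 400) {
  stopifnot(L >= 2)
  params <- with_local_seed(seed, {
    hidden <- sample(0:19, L, replace = TRUE)
    w <- stats::runif(L, 0.5, 1.5)           # per-position match weights
    pairs <- cbind(sample(L, epistasis_pairs, replace = TRUE),
                   sample(L, epistasis_pairs, replace = TRUE))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    eps_w <- stats::rnorm(nrow(pairs), 0, 0.35)
    # epistasis rewards residue-pair parity classes; zero contribution at
    # the hidden sequence keeps the maximum there by construction
    eps_c <- (hidden[pairs[, 1]] + hidden[pairs[, 2]]) %% 5
    list(hidden = hidden, w = w, pairs = pairs, eps_w = eps_w, eps_c = eps_c)
  })

  components <- function(X) {
    X <- as_points(X)
    if (ncol(X) != L) stop("sequence length mismatch", call. = FALSE)
    match_frac <- as.numeric((X == matrix(params$hidden, nrow(X), L,
                                          byrow = TRUE)) %*% params$w) /
      sum(params$w)
    # epistasis penalty is zero exactly when a pair's residue-sum parity
    # class matches the hidden sequence's, so the hidden sequence stays the
    # unique constructed maximum while off-target parity matches create
    # local optima
    epi <- vapply(seq_len(nrow(X)), function(i) {
      cls <- (X[i, params$pairs[, 1]] + X[i, params$pairs[, 2]]) %% 5
      -sum(abs(params$eps_w) * (cls != params$eps_c))
    }, numeric(1)) / max(length(params$eps_w), 1)
    sc <- stats::plogis(sc_gain * (2 * match_frac - 1) + epi)
    dsasa <- dsasa_base + dsasa_spread * match_frac
    tibble::tibble(sc = sc, dsasa = dsasa, target = sc * dsasa / 100)
  }

  obj <- objective(sprintf("synthetic-binder-L%d", L),
                   fn = function(X) components(X)$target,
                   direction = "maximize", d = L,
                   optimum = list(location = params$hidden,
                                  value = components(matrix(params$hidden,
                                                            1))$target[[1]]))
  obj$hidden <- params$hidden
  obj$score_components <- components
  obj
}

#' Write a candidate batch as FASTA
#'
#' Record ids are `<run>/<iteration>/<index>` so scores can be joined back
#' unambiguously.
#'
#' @param batch Sequence candidates (codes; matrix or data frame).
#' @param file Output path.
#' @param run,iteration Identifiers baked into the record ids.
#' @return Invisibly, the record ids.
#' @export
write_batch_fasta <- function(batch, file, run = "run", iteration = 0) {
  codes <- as_points(batch)
  ids <- sprintf("%s/%d/%d", run, iteration, seq_len(nrow(codes)))
  seqs <- codes_to_aa(codes)
  if (requireNamespace("seqinr", quietly = TRUE)) {
    seqinr::write.fasta(as.list(seqs), names = ids, file.out = file,
                        as.string = TRUE)
  } else {
    writeLines(paste0(">", ids, "\n", seqs), file)
  }
  invisible(ids)
}

#' Read sequences back from FASTA
#'
#' @param file FASTA path.
#' @return List with `ids` and the integer code matrix `codes`.
#' @export
read_batch_fasta <- function(file) {
  lines <- readLines(file)
  heads <- grepl("^>", lines)
  ids <- sub("^>\\s*", "", lines[heads])
  ids <- sub("\\s.*$", "", ids)
  grp <- cumsum(heads)
  seqs <- vapply(split(lines[!heads], grp[!heads]),
                 function(x) paste(x, collapse = ""), character(1))
  list(ids = ids, codes = aa_to_codes(unname(seqs)))
}

#' Label sequences through an external scoring executable
#'
#' The contract of a pluggable structure-based oracle: the batch is written
#' to a FASTA file, the configured command is invoked as
#' `command <fasta> <scores_out>`, and a two-column tab-separated table
#' (record id, score) is read back. Scores are aligned to batch order;
#' candidates whose id is missing from the table get `NA` and are reported
#' in the `failed` attribute.
#'
#' @param batch Sequence candidates (codes).
#' @param command Path to the scoring executable/script.
#' @param workdir Directory for the temporary FASTA/score files.
#' @param run,iteration Identifiers for the FASTA record ids.
#' @return Numeric score vector aligned to `batch`, with attribute
#'   `failed` (integer indices of unscored candidates).
#' @export
external_oracle_adapter <- function(batch, command, workdir = tempdir(),
                                    run = "run", iteration = 0) {
  if (!file.exists(command)) {
    stop(sprintf("oracle executable not found: %s", command), call. = FALSE)
  }
  fasta <- file.path(workdir, sprintf("%s_it%d.fasta", run, iteration))
  scores_file <- file.path(workdir, sprintf("%s_it%d.scores.tsv", run, iteration))
  ids <- write_batch_fasta(batch, fasta, run, iteration)
  status <- system2(command, c(fasta, scores_file))
  if (!identical(status, 0L)) {
    stop(sprintf("oracle command failed with status %s", status), call. = FALSE)
  }
  lines <- readLines(scores_file)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0) {
    stop(sprintf("malformed score table at line %d: '%s'", bad[1], lines[bad[1]]),
         call. = FALSE)
  }
  tab <- stats::setNames(
    suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2))),
    vapply(parts, `[[`, character(1), 1))
  out <- unname(tab[ids])
  failed <- which(is.na(out))
  if (length(failed) > 0) {
    warning(sprintf("%d candidate(s) missing from the score table", length(failed)))
  }
  attr(out, "failed") <- failed
  out
}
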