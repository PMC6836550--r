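#' Analyze a breakpoint-junction sequence
#'
#' Decomposes a sequenced junction into microhomology, inserted sequence,
#' and templated fragments. Conventions: `ref_a` is the reference sequence
#' around breakend A oriented as it appears in the derivative, with the
#' retained sequence ending at offset `bp_a` (1-based, inclusive) and the
#' reference continuing beyond the breakpoint afterwards; `ref_b` is the
#' reference around breakend B with the retained sequence starting at
#' offset `bp_b`. `junction_seq` runs across the transition in the same
#' orientation.
#'
#' The maximal prefix of `junction_seq` matching reference A (anchored at
#' the breakpoint, then extended into the reference continuation) and the
#' maximal suffix matching reference B are computed; where the two matches
#' overlap and both references agree the overlap is microhomology, where a
#' gap remains between them the gap is the inserted sequence. The two are
#' mutually exclusive at a single junction. Each maximal substring of the
#' insertion of length at least `min_templated` found exactly — on either
#' strand — in any of the `cluster_context` sequences (reference flanks of
#' the cluster's breakpoints, typically +/- 1 kb) is reported as a
#' templated fragment; replicative repair signatures are inferred from
#' these by [infer_mechanism()].
#'
#' @param ref_a,ref_b Reference flank sequences (see Details); each must be
#'   at least as long as `junction_seq`.
#' @param junction_seq Sequenced junction crossing the transition.
#' @param bp_a Offset in `ref_a` of the last retained base.
#' @param bp_b Offset in `ref_b` of the first retained base.
#' @param cluster_context Character vector of breakpoint-flank sequences to
#'   search for insertion templates.
#' @param min_templated Minimum exact-match length for a templated fragment
#'   (default 10 bp, making chance 4-letter matches improbable).
#' @return A `junction_analysis` list: `microhomology_len`, `inserted_seq`,
#'   `templated_fragments` (data frame: fragment, context, start, end,
#'   strand), `nontemplated_len`.
#' @export
analyze_junction <- function(ref_a, ref_b, junction_seq, bp_a, bp_b,
                             cluster_context = character(),
                             min_templated = 10) {
  m <- nchar(junction_seq)
  stopifnot(m > 0, bp_a >= 1, bp_a <= nchar(ref_a),
            bp_b >= 1, bp_b <= nchar(ref_b))
  if (nchar(ref_a) < m || nchar(ref_b) < m) {
    stop("flanks must be at least as long as the junction sequence",
         call. = FALSE)
  }
  a_ret <- substr(ref_a, 1, bp_a)
  a_ext <- substr(ref_a, bp_a + 1, nchar(ref_a))
  b_ret <- substr(ref_b, bp_b, nchar(ref_b))
  b_ext <- substr(ref_b, 1, bp_b - 1)

  # anchor: longest junction prefix equal to a suffix of the retained A
  s_a <- anchored_suffix_match(a_ret, junction_seq)
  if (s_a < min(10, bp_a, m)) {
    stop("junction sequence does not align to the A-side flank", call. = FALSE)
  }
  p <- s_a + common_prefix_len(substr(junction_seq, s_a + 1, m), a_ext)

  s_b <- anchored_prefix_match(b_ret, junction_seq)
  if (s_b < min(10, nchar(b_ret), m)) {
    stop("junction sequence does not align to the B-side flank", call. = FALSE)
  }
  q <- s_b + common_suffix_len(substr(junction_seq, 1, m - s_b), b_ext)

  gap <- m - p - q
  if (gap > 0) {
    inserted <- substr(junction_seq, p + 1, m - q)
    mh <- 0L
  } else {
    inserted <- ""
    mh <- as.integer(-gap)
  }

  frags <- find_templated(inserted, cluster_context, min_templated)
  templ_len <- if (nrow(frags)) sum(nchar(frags$fragment)) else 0L
  structure(list(
    microhomology_len = mh,
    inserted_seq = inserted,
    templated_fragments = frags,
    nontemplated_len = nchar(inserted) - templ_len
  ), class = "junction_analysis")
}

# longest k with junction[1..k] == last k chars of a_ret
anchored_suffix_match <- function(a_ret, junction) {
  kmax <- min(nchar(a_ret), nchar(junction))
  for (k in kmax:0) {
    if (k == 0L) return(0L)
    if (substr(junction, 1, k) ==
        substr(a_ret, nchar(a_ret) - k + 1, nchar(a_ret))) {
      return(k)
    }
  }
}

# longest k with junction[m-k+1..m] == first k chars of b_ret
anchored_prefix_match <- function(b_ret, junction) {
  m <- nchar(junction)
  kmax <- min(nchar(b_ret), m)
  for (k in kmax:0) {
    if (k == 0L) return(0L)
    if (substr(junction, m - k + 1, m) == substr(b_ret, 1, k)) {
      return(k)
    }
  }
}

# Greedy maximal decomposition of the insertion into fragments found
# exactly (either strand) in the context sequences.
find_templated <- function(inserted, contexts, min_templated) {
  empty <- data.frame(fragment = character(), context = integer(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  n <- nchar(inserted)
  if (n < min_templated || length(contexts) == 0L) return(empty)
  rc_contexts <- revcomp(contexts)
  out <- list()
  i <- 1L
  while (i + min_templated - 1L <= n) {
    best_len <- 0L
    best <- NULL
    # longest fragment starting at i present in any context
    lo <- min_templated
    hi <- n - i + 1L
    for (len in seq(hi, lo)) {
      frag <- substr(inserted, i, i + len - 1L)
      for (ci in seq_along(contexts)) {
        fwd <- regexpr(frag, contexts[ci], fixed = TRUE)
        if (fwd > 0) {
          best <- data.frame(fragment = frag, context = ci,
                             start = as.integer(fwd),
                             end = as.integer(fwd) + len - 1L,
                             strand = "+", stringsAsFactors = FALSE)
          best_len <- len
          break
        }
        rev <- regexpr(frag, rc_contexts[ci], fixed = TRUE)
        if (rev > 0) {
          cl <- nchar(contexts[ci])
          best <- data.frame(fragment = frag, context = ci,
                             start = cl - (as.integer(rev) + len - 1L) + 1L,
                             end = cl - as.integer(rev) + 1L,
                             strand = "-", stringsAsFactors = FALSE)
          best_len <- len
          break
        }
      }
      if (best_len > 0L) break
    }
    if (best_len > 0L) {
      out[[length(out) + 1L]] <- best
      i <- i + best_len
    } else {
      i <- i + 1L
    }
  }
  if (length(out)) do.call(rbind, out) else empty
}

#' Infer the formation mechanism of a rearrangement
#'
#' Encodes the qualitative junction-signature reasoning of clinical
#' breakpoint analysis as fixed, configurable rules, applied in order:
#' \enumerate{
#'   \item recurrent and repeat-flanked events are called `NAHR-like`
#'     (non-allelic homologous recombination between flanking repeats);
#'   \item any junction carrying a templated insertion fragment of at
#'     least `min_templated` bp is `replicative-like` (template switching
#'     during replication, FoSTeS/MMBIR-style);
#'   \item junctions that all show microhomology of at most `max_mh` bp
#'     and non-templated insertions of at most `max_ins` bp are
#'     `NHEJ-like` (blunt or near-blunt end joining);
#'   \item anything else is `unclassified`.
#' }
#' Repeat annotation is an input flag: recurrence is established from
#' locus knowledge, not computed here.
#'
#' @param junctions List of [analyze_junction()] results.
#' @param recurrent Is the event a known recurrent rearrangement?
#' @param repeat_flanked Are the breakpoints flanked by homologous repeats?
#' @param min_templated,max_mh,max_ins Rule thresholds.
#' @return A `mechanism_call`: `list(label, evidence)`.
#' @export
infer_mechanism <- function(junctions, recurrent = FALSE,
                            repeat_flanked = FALSE, min_templated = 10,
                            max_mh = 4, max_ins = 20) {
  stopifnot(length(junctions) >= 1)
  evidence <- character(0)
  if (recurrent && repeat_flanked) {
    return(mechanism_call("NAHR-like",
                          "recurrent event with repeat-flanked breakpoints"))
  }
  templ <- vapply(junctions, function(j) {
    nrow(j$templated_fragments) > 0 &&
      any(nchar(j$templated_fragments$fragment) >= min_templated)
  }, logical(1))
  if (any(templ)) {
    return(mechanism_call("replicative-like", sprintf(
      "templated insertion fragment(s) >= %d bp in %d junction(s)",
      min_templated, sum(templ))))
  }
  mh <- vapply(junctions, `[[`, numeric(1), "microhomology_len")
  ins <- vapply(junctions, function(j) nchar(j$inserted_seq), numeric(1))
  if (all(mh <= max_mh) && all(ins <= max_ins)) {
    return(mechanism_call("NHEJ-like", sprintf(
      "microhomology <= %d bp and non-templated insertions <= %d bp across %d junction(s)",
      max_mh, max_ins, length(junctions))))
  }
  mechanism_call("unclassified",
                 "junction signatures match no configured mechanism rule")
}

mechanism_call <- function(label, evidence) {
  structure(list(label = label, evidence = evidence),
            class = "mechanism_call")
}

#' Simulate a breakpoint junction with known microhomology/insertion
#'
#' Constructs random reference flanks and a junction sequence whose true
#' microhomology and insertion are exactly the requested values: the bases
#' adjacent to the transition are resampled until no accidental
#' single-base extension of either anchored match exists, so the planted
#' values are the ground truth, not merely the construction parameters.
#' Optionally the insertion embeds a fragment copied (reverse-complemented
#' or not) from a supplied context sequence, for templated-insertion
#' studies.
#'
#' @param mh Microhomology length (ignored unless `ins_len == 0`).
#' @param ins_len Inserted-sequence length (microhomology and insertion
#'   are mutually exclusive).
#' @param flank_len Length of retained sequence on each side.
#' @param seed Integer seed.
#' @param template Optional list `list(context = <sequence>, len = <bp>,
#'   strand = "+"/"-")`: embed a fragment of the context in the insertion.
#' @return List with `ref_a`, `ref_b`, `bp_a`, `bp_b`, `junction_seq`,
#'   `mh`, `ins` — ready for [analyze_junction()].
#' @export
simulate_junction <- function(mh = 0, ins_len = 0, flank_len = 200,
                              seed = 1, template = NULL) {
  stopifnot(mh >= 0, ins_len >= 0, flank_len > 2 * (mh + 10),
            flank_len >= ins_len + 20)
  if (mh > 0 && ins_len > 0) {
    stop("microhomology and insertion are mutually exclusive at one junction",
         call. = FALSE)
  }
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  resample_not <- function(avoid) sample(setdiff(bases, avoid), 1)

  a_ret <- random_dna(flank_len)
  b_ret <- random_dna(flank_len)
  a_ext <- random_dna(flank_len)
  b_ext <- random_dna(flank_len)

  if (mh > 0) {
    h <- random_dna(mh)
    substr(a_ret, flank_len - mh + 1, flank_len) <- h
    substr(b_ret, 1, mh) <- h
  }
  ins <- ""
  if (ins_len > 0) {
    if (!is.null(template)) {
      tl <- min(template$len, ins_len)
      frag <- substr(template$context, 1, tl)
      if (identical(template$strand, "-")) frag <- revcomp(frag)
      ins <- paste0(frag, random_dna(ins_len - tl))
    } else {
      ins <- random_dna(ins_len)
    }
  }

  # guard the four transition-adjacent bases against accidental extension
  first_after_a <- if (ins_len > 0) substr(ins, 1, 1) else
    substr(b_ret, mh + 1, mh + 1)
  if (substr(a_ext, 1, 1) == first_after_a) {
    substr(a_ext, 1, 1) <- resample_not(first_after_a)
  }
  last_before_b <- if (ins_len > 0) substr(ins, ins_len, ins_len) else
    substr(a_ret, flank_len - mh, flank_len - mh)
  if (substr(b_ext, flank_len, flank_len) == last_before_b) {
    substr(b_ext, flank_len, flank_len) <- resample_not(last_before_b)
  }

  # the sequenced junction carries half a flank on each side, so the
  # reference flanks (one flank retained + one continuation) always exceed
  # the junction length as analyze_junction() requires
  j_flank <- floor(flank_len / 2)
  junction_seq <- paste0(substr(a_ret, flank_len - j_flank + 1, flank_len),
                         ins, substr(b_ret, mh + 1, mh + j_flank))
  list(ref_a = paste0(a_ret, a_ext), ref_b = paste0(b_ext, b_ret),
       bp_a = flank_len, bp_b = flank_len + 1, junction_seq = junction_seq,
       mh = as.integer(mh), ins = ins)
}
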