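#' Cluster structural variants into candidate rearrangements
#'
#' Groups SV records that plausibly belong to one genomic rearrangement:
#' records on the same chromosome whose intervals lie within `max_gap` of
#' each other cluster together, and clusters are additionally unioned when
#' joined by an interchromosomal breakend (a BND record links its own locus
#' with records near its partner locus). Singletons are allowed.
#'
#' @param records [sv_records()] table.
#' @param max_gap Maximum intervening distance in bp (default 1 Mb).
#' @return List of `sv_cluster` objects (each `list(records = ...)`).
#' @export
cluster_rearrangements <- function(records, max_gap = 1e6) {
  stopifnot(max_gap >= 0)
  n <- nrow(records)
  if (n == 0L) return(list())
  uf <- uf_new(n)
  gap <- function(s1, e1, s2, e2) max(0, max(s1, s2) - min(e1, e2))
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (b <= a) next
      near <- records$chrom[a] == records$chrom[b] &&
        gap(records$start[a], records$end[a],
            records$start[b], records$end[b]) <= max_gap
      if (!near && !is.na(records$partner_chrom[a])) {
        near <- records$partner_chrom[a] == records$chrom[b] &&
          gap(records$partner_pos[a], records$partner_pos[a],
              records$start[b], records$end[b]) <= max_gap
      }
      if (!near && !is.na(records$partner_chrom[b])) {
        near <- records$partner_chrom[b] == records$chrom[a] &&
          gap(records$partner_pos[b], records$partner_pos[b],
              records$start[a], records$end[a]) <= max_gap
      }
      if (!near && !is.na(records$partner_chrom[a]) &&
          !is.na(records$partner_chrom[b])) {
        near <- records$partner_chrom[a] == records$partner_chrom[b] &&
          abs(records$partner_pos[a] - records$partner_pos[b]) <= max_gap
      }
      if (near) uf <- uf_union(uf, a, b)
    }
  }
  comp <- uf_components(uf)
  lapply(split(seq_len(n), comp), function(ix) {
    r <- records[ix, , drop = FALSE]
    rownames(r) <- NULL
    structure(list(records = r), class = "sv_cluster")
  })
}

# --- breakend/junction derivation -------------------------------------------
#
# A breakend is (chrom, pos, side) where side is the reference side retained
# at the join: "L" = sequence left of pos is retained (the join continues to
# the right of the retained sequence), "R" = sequence right of pos retained.
# A junction pairs two breakends. Record types imply junctions on the
# derivative haplotype:
#   DEL s-e : ((chrom,s,L),(chrom,e,R))       -- flanks fused, segment lost
#   DUP s-e : ((chrom,e,L),(chrom,s,R))       -- head-to-tail (tandem) join
#   INV s-e : ((chrom,s,L),(chrom,e,L)) and ((chrom,s,R),(chrom,e,R))
#   BND     : sides taken from partner_orient (local then partner letter)
# DEL/DUP junctions are only added when no breakend evidence touches the
# record's boundaries (otherwise the BNDs describe the join: insertion
# sites, translocation fusions, ring closures). Terminal deletions have no
# flank fusion and contribute no junction either.
derive_junctions <- function(records, tol = 10, genome = NULL) {
  jl <- list()
  add <- function(c1, p1, s1, c2, p2, s2) {
    jl[[length(jl) + 1L]] <<- data.frame(
      c1 = c1, p1 = p1, s1 = s1, c2 = c2, p2 = p2, s2 = s2,
      stringsAsFactors = FALSE)
  }
  bnds <- records[records$sv_type == "BND", , drop = FALSE]
  seen <- character(0)
  if (nrow(bnds) > 0) {
    for (i in seq_len(nrow(bnds))) {
      r <- bnds[i, ]
      if (is.na(r$partner_orient)) next
      s1 <- substr(r$partner_orient, 1, 1)
      s2 <- substr(r$partner_orient, 2, 2)
      e1 <- sprintf("%s:%.0f:%s", r$chrom, r$start, s1)
      e2 <- sprintf("%s:%.0f:%s", r$partner_chrom, r$partner_pos, s2)
      key <- paste(sort(c(e1, e2)), collapse = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      add(r$chrom, r$start, s1, r$partner_chrom, r$partner_pos, s2)
    }
  }
  bnd_pts <- if (nrow(bnds)) c(bnds$start, bnds$partner_pos) else numeric(0)
  bnd_ctg <- if (nrow(bnds)) c(bnds$chrom, bnds$partner_chrom) else character(0)
  touches_bnd <- function(chrom, pos) {
    any(bnd_ctg == chrom & abs(bnd_pts - pos) <= tol)
  }
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$sv_type == "DEL") {
      terminal <- r$start <= 0 ||
        (!is.null(genome) && r$chrom %in% names(genome) &&
           r$end >= genome[[r$chrom]])
      if (!terminal && !touches_bnd(r$chrom, r$start) &&
          !touches_bnd(r$chrom, r$end)) {
        add(r$chrom, r$start, "L", r$chrom, r$end, "R")
      }
    } else if (r$sv_type == "INV") {
      add(r$chrom, r$start, "L", r$chrom, r$end, "L")
      add(r$chrom, r$start, "R", r$chrom, r$end, "R")
    } else if (r$sv_type == "DUP") {
      if (!touches_bnd(r$chrom, r$start) && !touches_bnd(r$chrom, r$end)) {
        add(r$chrom, r$end, "L", r$chrom, r$start, "R")
      }
    }
  }
  if (length(jl) == 0L) {
    return(data.frame(c1 = character(), p1 = numeric(), s1 = character(),
                      c2 = character(), p2 = numeric(), s2 = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, jl)
}

# Segment table: per chromosome, tile [0, len] at every breakpoint; copy
# count on the derivative haplotype = 1 + (# DUPs covering) - (deleted).
derive_segments <- function(records, junctions, genome) {
  chroms <- unique(c(records$chrom, records$partner_chrom,
                     junctions$c1, junctions$c2))
  chroms <- chroms[!is.na(chroms)]
  missing <- setdiff(chroms, names(genome))
  if (length(missing)) {
    stop("contig(s) absent from genome table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  segs <- list()
  for (ctg in chroms) {
    len <- genome[[ctg]]
    cuts <- c(0, len,
              junctions$p1[junctions$c1 == ctg],
              junctions$p2[junctions$c2 == ctg],
              records$start[records$chrom == ctg & records$sv_type != "BND"],
              records$end[records$chrom == ctg & records$sv_type != "BND"])
    cuts <- sort(unique(pmin(pmax(cuts, 0), len)))
    if (length(cuts) < 2L) next
    st <- cuts[-length(cuts)]
    en <- cuts[-1]
    mid <- (st + en) / 2
    copies <- rep(1L, length(st))
    for (i in which(records$chrom == ctg)) {
      r <- records[i, ]
      inside <- mid > r$start & mid < r$end
      if (r$sv_type == "DUP") copies[inside] <- copies[inside] + 1L
      if (r$sv_type == "DEL") copies[inside] <- 0L
    }
    segs[[ctg]] <- data.frame(chrom = ctg, start = st, end = en,
                              copies = copies, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

# One traversal of the breakend graph, with backtracking: where several
# junctions share a breakend (clustered SVs with common breakpoints) every
# continuation is explored and the walk consuming the most junctions — and
# among those, one that ends cleanly at a telomere or ring closure — wins.
# Returns the emitted path, consumed junction indices, updated state and
# status flags.
walk_breakends <- function(segs, juncs, chrom, pos, dir,
                           init_breakend = NULL, max_nodes = 5000L) {
  nodes <- 0L
  better <- function(a, b) {
    if (is.null(b)) return(TRUE)
    if (length(a$consumed) != length(b$consumed)) {
      return(length(a$consumed) > length(b$consumed))
    }
    if (a$blocked != b$blocked) return(!a$blocked)
    FALSE
  }
  rec <- function(segs, juncs, chrom, pos, dir, path, consumed) {
    repeat {
      nodes <<- nodes + 1L
      done <- function(circular = FALSE, blocked = FALSE) {
        list(path = path, consumed = consumed, segs = segs, juncs = juncs,
             circular = circular, blocked = blocked)
      }
      if (nodes > max_nodes) return(done(blocked = TRUE))
      seg_i <- if (dir > 0) {
        which(segs$chrom == chrom & segs$start == pos)
      } else {
        which(segs$chrom == chrom & segs$end == pos)
      }
      if (length(seg_i) == 0L) return(done())          # telomere
      if (segs$copies[seg_i] <= 0L) {
        return(done(blocked = length(path) > 0L))      # dead end
      }
      segs$copies[seg_i] <- segs$copies[seg_i] - 1L
      path[[length(path) + 1L]] <- data.frame(
        chrom = chrom, start = segs$start[seg_i], end = segs$end[seg_i],
        orient = if (dir > 0) "+" else "-", stringsAsFactors = FALSE)
      pos <- if (dir > 0) segs$end[seg_i] else segs$start[seg_i]
      side <- if (dir > 0) "L" else "R"
      if (!is.null(init_breakend) &&
          init_breakend$chrom == chrom && init_breakend$pos == pos &&
          init_breakend$side == side) {
        return(done(circular = TRUE))
      }
      hits <- which(!juncs$consumed &
                      ((juncs$c1 == chrom & juncs$p1 == pos & juncs$s1 == side) |
                         (juncs$c2 == chrom & juncs$p2 == pos &
                            juncs$s2 == side)))
      if (length(hits) == 0L) next  # reference adjacency, same direction
      best <- NULL
      for (j in hits) {
        juncs2 <- juncs
        juncs2$consumed[j] <- TRUE
        at_end1 <- juncs$c1[j] == chrom & juncs$p1[j] == pos &
          juncs$s1[j] == side
        if (at_end1) {
          nchrom <- juncs$c2[j]; npos <- juncs$p2[j]
          ndir <- if (juncs$s2[j] == "R") 1L else -1L
        } else {
          nchrom <- juncs$c1[j]; npos <- juncs$p1[j]
          ndir <- if (juncs$s1[j] == "R") 1L else -1L
        }
        cand <- rec(segs, juncs2, nchrom, npos, ndir, path, c(consumed, j))
        if (better(cand, best)) best <- cand
      }
      # passing straight through the breakend is also admissible
      cand <- rec(segs, juncs, chrom, pos, dir, path, consumed)
      if (better(cand, best)) best <- cand
      return(best)
    }
  }
  out <- rec(segs, juncs, chrom, pos, dir, list(), integer(0))
  out$path <- if (length(out$path)) do.call(rbind, out$path) else NULL
  out
}

finish_structure <- function(path, circular, incomplete) {
  segments <- merge_colinear(path)
  segments <- canonical_orientation(segments, circular)
  structure(list(segments = segments, circular = circular,
                 incomplete = incomplete),
            class = "derivative_structure")
}

merge_colinear <- function(path) {
  if (is.null(path) || nrow(path) <= 1L) return(path)
  out <- path[1, , drop = FALSE]
  for (i in 2:nrow(path)) {
    last <- nrow(out)
    joinable <- out$chrom[last] == path$chrom[i] &&
      out$orient[last] == path$orient[i] &&
      ((path$orient[i] == "+" && out$end[last] == path$start[i]) ||
         (path$orient[i] == "-" && out$start[last] == path$end[i]))
    if (joinable) {
      if (path$orient[i] == "+") out$end[last] <- path$end[i]
      else out$start[last] <- path$start[i]
    } else {
      out <- rbind(out, path[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

# Present linear walks telomere-to-telomere in a fixed reading direction so
# the output does not depend on which telomere the walk happened to start
# from (mirror-image invariance).
canonical_orientation <- function(segments, circular) {
  if (is.null(segments) || nrow(segments) == 0L || circular) return(segments)
  first <- segments[1, ]; last <- segments[nrow(segments), ]
  key <- function(s) sprintf("%s:%020.0f", s$chrom, min(s$start, s$end))
  if (key(last) < key(first)) {
    segments <- segments[rev(seq_len(nrow(segments))), , drop = FALSE]
    segments$orient <- ifelse(segments$orient == "+", "-", "+")
    rownames(segments) <- NULL
  }
  segments
}

#' Reconstruct derivative chromosomes from a rearrangement cluster
#'
#' Builds a graph whose nodes are segment boundaries, with reference
#' adjacencies and the breakpoint junctions implied by the cluster's
#' records (see the breakend conventions in the package source), then
#' walks telomere to telomere consuming each junction once. Duplicated
#' segments are traversed once per copy; deleted segments are absent. A
#' closed walk yields a ring (`circular = TRUE`). When junctions remain
#' that no telomere-anchored walk can consume, reconstruction restarts
#' from the junction itself; a walk that returns to its starting breakend
#' is circular, anything left dangling is returned flagged `incomplete`.
#'
#' @param cluster An `sv_cluster` (from [cluster_rearrangements()]) or an
#'   [sv_records()] table.
#' @param genome Named vector of contig lengths.
#' @return List of `derivative_structure` objects, each
#'   `list(segments = data.frame(chrom, start, end, orient), circular,
#'   incomplete)`.
#' @export
reconstruct_derivative <- function(cluster, genome) {
  records <- if (inherits(cluster, "sv_cluster")) cluster$records else cluster
  juncs <- derive_junctions(records, genome = genome)
  juncs$consumed <- rep(FALSE, nrow(juncs))
  segs <- derive_segments(records, juncs, genome)
  structures <- list()

  telomere_starts <- function() {
    out <- list()
    for (ctg in unique(segs$chrom)) {
      len <- max(segs$end[segs$chrom == ctg])
      out[[length(out) + 1L]] <- list(chrom = ctg, pos = 0, dir = 1L)
      out[[length(out) + 1L]] <- list(chrom = ctg, pos = len, dir = -1L)
    }
    out[order(vapply(out, function(s) sprintf("%s:%020.0f", s$chrom, s$pos),
                     character(1)))]
  }

  # Phase 1: telomere-anchored walks that consume junctions, best-first.
  while (any(!juncs$consumed)) {
    trials <- lapply(telomere_starts(), function(s) {
      walk_breakends(segs, juncs, s$chrom, s$pos, s$dir)
    })
    gains <- vapply(trials, function(t) length(t$consumed), integer(1))
    if (max(gains) == 0L) break
    best <- trials[[which.max(gains)]]
    segs <- best$segs; juncs <- best$juncs
    structures[[length(structures) + 1L]] <-
      finish_structure(best$path, circular = FALSE, incomplete = best$blocked)
  }

  # Phase 2: walks initiated at an unconsumed junction (rings, fragments).
  while (any(!juncs$consumed)) {
    j <- which(!juncs$consumed)[1]
    juncs$consumed[j] <- TRUE
    init <- list(chrom = juncs$c1[j], pos = juncs$p1[j], side = juncs$s1[j])
    dir <- if (juncs$s2[j] == "R") 1L else -1L
    w <- walk_breakends(segs, juncs, juncs$c2[j], juncs$p2[j], dir,
                        init_breakend = init)
    segs <- w$segs; juncs <- w$juncs
    structures[[length(structures) + 1L]] <-
      finish_structure(w$path, circular = w$circular,
                       incomplete = !w$circular)
  }

  # Phase 3: residual reference material (e.g. the unrearranged homolog of
  # a duplication donor) emitted as plain linear structures.
  repeat {
    trials <- lapply(telomere_starts(), function(s) {
      walk_breakends(segs, juncs, s$chrom, s$pos, s$dir)
    })
    lens <- vapply(trials, function(t) if (is.null(t$path)) 0L else nrow(t$path),
                   integer(1))
    if (max(lens) == 0L) break
    best <- trials[[which.max(lens)]]
    segs <- best$segs; juncs <- best$juncs
    structures[[length(structures) + 1L]] <-
      finish_structure(best$path, circular = FALSE, incomplete = best$blocked)
  }
  if (any(segs$copies > 0L)) {
    # orphaned interior material (dangling junction geometry)
    for (i in which(segs$copies > 0L)) {
      reps <- segs$copies[i]
      for (k in seq_len(reps)) {
        structures[[length(structures) + 1L]] <- finish_structure(
          data.frame(chrom = segs$chrom[i], start = segs$start[i],
                     end = segs$end[i], orient = "+",
                     stringsAsFactors = FALSE),
          circular = FALSE, incomplete = TRUE)
      }
    }
  }
  structures
}

#' @export
print.derivative_structure <- function(x, ...) {
  kind <- if (x$circular) "ring" else "linear"
  flag <- if (x$incomplete) " [incomplete]" else ""
  cat(sprintf("derivative structure (%s, %d segment(s))%s\n",
              kind, NROW(x$segments), flag))
  if (!is.null(x$segments)) {
    with(x$segments, cat(sprintf("  %s:%s-%s %s\n", chrom,
                                 format(start, scientific = FALSE),
                                 format(end, scientific = FALSE), orient),
                         sep = ""))
  }
  invisible(x)
}

#' Classify the topology of a reconstructed rearrangement
#'
#' Deterministic rule table over the cluster's record composition,
#' junctions and reconstructed structures, using the label vocabulary of
#' clinical derivative-chromosome reporting. The classification is
#' invariant to record order and to mirror-image presentation.
#'
#' @param structures List from [reconstruct_derivative()].
#' @param cluster `sv_cluster` or [sv_records()] table.
#' @return One of `simple-DEL`, `tandem-DUP`, `DEL-INV-DEL`,
#'   `DUP-NML-DUP`, `DEL-NML-DEL`, `insertional-translocation`,
#'   `unbalanced-translocation`, `reciprocal-translocation`, `ring`,
#'   `other-complex`.
#' @export
classify_structure <- function(structures, cluster) {
  records <- if (inherits(cluster, "sv_cluster")) cluster$records else cluster
  if (any(vapply(structures, function(s) isTRUE(s$circular), logical(1)))) {
    return("ring")
  }
  juncs <- derive_junctions(records)
  chroms <- unique(c(records$chrom, stats::na.omit(records$partner_chrom)))
  dels <- records[records$sv_type == "DEL", , drop = FALSE]
  dups <- records[records$sv_type == "DUP", , drop = FALSE]
  invs <- records[records$sv_type == "INV", , drop = FALSE]

  if (length(chroms) == 2L) {
    inter <- juncs[juncs$c1 != juncs$c2, , drop = FALSE]
    # an inserted segment is stitched in at both edges; a single
    # interchromosomal fusion is a translocation, not an insertion
    if (nrow(dups) > 0 && nrow(inter) >= 2) {
      for (i in seq_len(nrow(dups))) {
        if (duplication_topology(dups[i, ], records) == "inserted") {
          return("insertional-translocation")
        }
      }
    }
    if (nrow(inter) >= 2L) {
      pair <- t(apply(inter[, c("c1", "c2")], 1, sort))
      same_pair <- all(pair[, 1] == pair[1, 1] & pair[, 2] == pair[1, 2])
      if (same_pair) {
        sides_a <- ifelse(inter$c1 == pair[1, 1], inter$s1, inter$s2)
        sides_b <- ifelse(inter$c1 == pair[1, 1], inter$s2, inter$s1)
        if (all(c("L", "R") %in% sides_a) && all(c("L", "R") %in% sides_b)) {
          return("reciprocal-translocation")
        }
      }
    }
    if (nrow(inter) == 1L && nrow(dups) >= 1L && nrow(dels) >= 1L &&
        any(dups$chrom != dels$chrom[1])) {
      return("unbalanced-translocation")
    }
    return("other-complex")
  }

  if (length(chroms) == 1L) {
    nd <- nrow(dels); nu <- nrow(dups); ni <- nrow(invs)
    if (nd == 1L && nu == 0L && ni == 0L && nrow(records) == 1L) {
      return("simple-DEL")
    }
    if (nu == 1L && nd == 0L && ni == 0L) {
      topo <- duplication_topology(dups[1, ], records)
      if (topo != "inserted") return("tandem-DUP")
      return("other-complex")
    }
    if (nd == 2L && ni == 1L && nu == 0L) {
      d <- dels[order(dels$start), ]
      v <- invs[1, ]
      if (v$start >= d$end[1] - 1 && v$end <= d$start[2] + 1) {
        return("DEL-INV-DEL")
      }
    }
    if (nd == 2L && ni == 0L && nu == 0L) {
      d <- dels[order(dels$start), ]
      if (d$start[2] > d$end[1]) return("DEL-NML-DEL")
    }
    if (nu == 2L && ni == 0L && nd == 0L) {
      u <- dups[order(dups$start), ]
      if (u$start[2] > u$end[1]) return("DUP-NML-DUP")
    }
  }
  "other-complex"
}

#' Determine whether a duplication is tandem or inserted
#'
#' Uses the breakend evidence in the cluster: a junction joining the
#' duplication's right boundary back to its own left boundary in
#' head-to-tail orientation means a tandem duplication; breakend mates
#' landing outside the duplicated interval (typically on another
#' chromosome) mean the extra copy was inserted elsewhere; no junction
#' evidence leaves the topology unknown.
#'
#' @param dup One-row [sv_records()] table with `sv_type == "DUP"`.
#' @param junction_evidence [sv_records()] table containing the cluster's
#'   BND records (other record types are ignored).
#' @param tol Breakpoint match tolerance in bp.
#' @return `"tandem"`, `"inserted"` or `"unknown"`.
#' @export
duplication_topology <- function(dup, junction_evidence, tol = 10) {
  stopifnot(dup$sv_type == "DUP")
  bnds <- junction_evidence[junction_evidence$sv_type == "BND", , drop = FALSE]
  if (nrow(bnds) == 0L) return("unknown")
  near <- function(chrom, pos, target_chrom, target_pos) {
    chrom == target_chrom & abs(pos - target_pos) <= tol
  }
  at_boundary <- rep(FALSE, nrow(bnds))
  for (i in seq_len(nrow(bnds))) {
    b <- bnds[i, ]
    s1 <- substr(b$partner_orient, 1, 1)
    s2 <- substr(b$partner_orient, 2, 2)
    ends <- data.frame(chrom = c(b$chrom, b$partner_chrom),
                       pos = c(b$start, b$partner_pos),
                       side = c(s1, s2), stringsAsFactors = FALSE)
    # head-to-tail self-join: (dup_end, L) with (dup_start, R)
    tandem <- any(near(ends$chrom, ends$pos, dup$chrom, dup$end) &
                    ends$side == "L") &&
      any(near(ends$chrom, ends$pos, dup$chrom, dup$start) & ends$side == "R")
    if (tandem) return("tandem")
    touches <- near(ends$chrom, ends$pos, dup$chrom, dup$start) |
      near(ends$chrom, ends$pos, dup$chrom, dup$end)
    outside <- ends$chrom != dup$chrom |
      ends$pos < dup$start - tol | ends$pos > dup$end + tol
    if (any(touches) && any(outside & !touches)) at_boundary[i] <- TRUE
  }
  if (any(at_boundary)) "inserted" else "unknown"
}

#' Write derivative structures as a BED-like segment list
#'
#' One row per segment with an orientation column; structures separated by
#' track comment lines.
#'
#' @param structures List from [reconstruct_derivative()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_derivatives <- function(structures, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(structures)) {
    s <- structures[[i]]
    writeLines(sprintf("# structure %d circular=%s incomplete=%s", i,
                       tolower(s$circular), tolower(s$incomplete)), con)
    if (!is.null(s$segments)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", s$segments$chrom,
                         as.integer(s$segments$start),
                         as.integer(s$segments$end), s$segments$orient), con)
    }
  }
  invisible(path)
}
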