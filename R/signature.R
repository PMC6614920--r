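# Loop-receptor sequence signatures on the 23-position label scheme.
#
# Positions are labels, not indices: insertions get fractional labels
# ("6.1" sits between "6" and "7") and deletions are explicit "-" residues,
# so variants never need re-numbering.

RNA_BASES <- c("A", "C", "G", "U")
GAP <- "-"

# fixed long-range pairing map: loop 8-12 against receptor 3' strand 22-18
LOOP_RECEPTOR_PAIRS <- data.frame(
  loop_pos = as.character(8:12),
  receptor_pos = as.character(22:18),
  stringsAsFactors = FALSE
)

#' Sort position labels in signature order
#'
#' Labels are integer tokens ("1".."23") optionally with an insertion minor
#' index ("6.1"), ordered by (major, minor): "6" < "6.1" < "7".
#'
#' @param labels character vector of position labels.
#' @return `labels` sorted in signature order.
#' @export
sort_position_labels <- function(labels) {
  parts <- strsplit(as.character(labels), ".", fixed = TRUE)
  major <- vapply(parts, function(p) suppressWarnings(as.integer(p[[1L]])), 0L)
  minor <- vapply(parts, function(p)
    if (length(p) > 1L) suppressWarnings(as.integer(p[[2L]])) else 0L, 0L)
  if (any(is.na(major)) || any(is.na(minor)))
    stop("malformed position label(s): ",
         paste(labels[is.na(major) | is.na(minor)], collapse = ", "))
  labels[order(major, minor)]
}

#' Parse a tectoRNA construct name
#'
#' Construct names follow the field nomenclature: a base identifier (last
#' three digits of the source accession, or a crystal-structure id), an
#' optional `_9` / `_10` / `_11` stem-length token (default 11 bp), and an
#' optional `.k` artificial-variant suffix. `"980_9"` is the 980
#' loop-receptor on a 9-bp stem connector; `"4LVV_9.1"` is artificial
#' variant 1 of 4LVV on a 9-bp stem.
#'
#' @param name construct name, e.g. `"980"`, `"980_9"`, `"4LVV_9.1"`.
#' @return list with `base_id`, `stem_length_bp` (9, 10 or 11) and
#'   `variant_suffix` (`NA` when absent).
#' @export
parse_variant_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("name must be a non-empty string")
  m <- regmatches(name, regexec("^([^_.]+)(?:_([0-9]+))?(?:\\.([0-9]+))?$", name))[[1L]]
  if (length(m) == 0L || !nzchar(m[2L]))
    stop("malformed construct name: '", name, "'")
  stem <- if (nzchar(m[3L])) as.integer(m[3L]) else 11L
  if (!stem %in% c(9L, 10L, 11L))
    stop("malformed stem-length token '_", m[3L], "' in '", name,
         "': stem connector must be 9, 10 or 11 bp")
  list(base_id = m[2L],
       stem_length_bp = stem,
       variant_suffix = if (nzchar(m[4L])) m[4L] else NA_character_)
}

#' Construct a loop-receptor variant
#'
#' @param id construct name; parsed with [parse_variant_name()] for the
#'   stem-length annotation unless `stem_length_bp` is supplied.
#' @param residues named character vector: names are position labels,
#'   values are `A`/`C`/`G`/`U` or `"-"` for an explicit deletion.
#' @param source `"natural"` or `"artificial"`.
#' @param stem_length_bp optional override of the parsed stem length.
#' @return object of class `thf_variant`.
#' @export
thf_variant <- function(id, residues, source = c("natural", "artificial"),
                        stem_length_bp = NULL) {
  source <- match.arg(source)
  parsed <- parse_variant_name(id)
  if (is.null(names(residues)) || any(!nzchar(names(residues))))
    stop("residues must be a named vector keyed by position label")
  if (anyDuplicated(names(residues)))
    stop("duplicate position label(s): ",
         paste(unique(names(residues)[duplicated(names(residues))]), collapse = ", "))
  residues <- stats::setNames(toupper(as.character(residues)), names(residues))
  bad <- !residues %in% c(RNA_BASES, GAP)
  if (any(bad))
    stop("non-RNA residue(s) at ", paste(names(residues)[bad], collapse = ", "),
         ": ", paste(residues[bad], collapse = ", "))
  labels <- sort_position_labels(names(residues))
  structure(list(
    id = id,
    base_id = parsed$base_id,
    stem_length_bp = as.integer(stem_length_bp %||% parsed$stem_length_bp),
    variant_suffix = parsed$variant_suffix,
    source = source,
    residues = residues[labels]
  ), class = "thf_variant")
}

#' @export
print.thf_variant <- function(x, ...) {
  cat(sprintf("<thf_variant %s> stem=%d bp, %s\n", x$id, x$stem_length_bp, x$source))
  cat(" ", paste(names(x$residues), collapse = " "), "\n")
  cat(" ", paste(format(x$residues, width = nchar(names(x$residues))),
                 collapse = " "), "\n")
  invisible(x)
}

#' Classify a base combination in the long-range pairing
#'
#' Watson-Crick pairs are A:U, U:A, G:C, C:G; wobble pairs are G:U and U:G;
#' any other base combination is a mismatch. A deleted partner (gap or `NA`)
#' makes the column `UNPAIRED`.
#'
#' @param base_loop,base_receptor single characters in `A`,`C`,`G`,`U`,
#'   or `"-"`/`NA` for a deleted position.
#' @return one of `"WATSON_CRICK"`, `"WOBBLE"`, `"MISMATCH"`, `"UNPAIRED"`.
#' @export
classify_pair <- function(base_loop, base_receptor) {
  norm <- function(b) {
    if (length(b) != 1L) stop("bases must be single characters")
    if (is.na(b) || b == GAP) return(NA_character_)
    b <- toupper(b)
    if (!b %in% RNA_BASES) stop("non-RNA base: '", b, "'")
    b
  }
  a <- norm(base_loop); b <- norm(base_receptor)
  if (is.na(a) || is.na(b)) return("UNPAIRED")
  key <- paste0(a, b)
  if (key %in% c("AU", "UA", "GC", "CG")) return("WATSON_CRICK")
  if (key %in% c("GU", "UG")) return("WOBBLE")
  "MISMATCH"
}

residue_at <- function(variant, label) {
  r <- variant$residues
  if (label %in% names(r)) unname(r[[label]]) else GAP
}

#' Long-range pairing profile of a variant
#'
#' Classifies the five loop-receptor pairs 8:22, 9:21, 10:20, 11:19, 12:18
#' and counts the G:C pairs among them (a correlate of tolerance to
#' non-canonical pairs elsewhere in the interaction).
#'
#' @param variant a [thf_variant()].
#' @return list with `pairs` (data.frame: loop_pos, receptor_pos, loop_base,
#'   receptor_base, class) and `gc_count`.
#' @export
pairing_profile <- function(variant) {
  stopifnot(inherits(variant, "thf_variant"))
  pairs <- LOOP_RECEPTOR_PAIRS
  pairs$loop_base <- vapply(pairs$loop_pos, residue_at, "", variant = variant)
  pairs$receptor_base <- vapply(pairs$receptor_pos, residue_at, "", variant = variant)
  pairs$class <- mapply(classify_pair, pairs$loop_base, pairs$receptor_base,
                        USE.NAMES = FALSE)
  gc <- sum(pairs$class == "WATSON_CRICK" &
              ((pairs$loop_base == "G" & pairs$receptor_base == "C") |
               (pairs$loop_base == "C" & pairs$receptor_base == "G")))
  list(pairs = pairs, gc_count = gc)
}

#' Point-mutation distance between two variants
#'
#' Counts alignment columns (the union of position labels) at which the two
#' variants differ; a residue aligned against a deletion or a missing label
#' counts as one mutation. Symmetric, and a metric on fixed-column variants.
#'
#' @param a,b [thf_variant()] objects.
#' @return non-negative integer.
#' @export
point_mutation_distance <- function(a, b) {
  stopifnot(inherits(a, "thf_variant"), inherits(b, "thf_variant"))
  labels <- sort_position_labels(union(names(a$residues), names(b$residues)))
  ra <- vapply(labels, residue_at, "", variant = a)
  rb <- vapply(labels, residue_at, "", variant = b)
  sum(ra != rb)
}

#' Group variants into sequence families
#'
#' Families are the connected components of the graph whose edges join
#' variants at [point_mutation_distance()] `<= max_distance`. Components are
#' returned largest first (ties broken by the lexicographically smallest
#' member id), members sorted by id; the result is invariant to input order.
#'
#' @param variants list of [thf_variant()] objects with unique ids.
#' @param max_distance edge threshold in point mutations (default 2).
#' @return list of character vectors of variant ids.
#' @export
family_components <- function(variants, max_distance = 2) {
  stopifnot(length(variants) >= 1L)
  ids <- unname(vapply(variants, function(v) v$id, ""))
  if (anyDuplicated(ids)) stop("variant ids must be unique")
  n <- length(variants)
  adj <- matrix(FALSE, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      adj[i, j] <- adj[j, i] <-
        point_mutation_distance(variants[[i]], variants[[j]]) <= max_distance
    }
  }
  seen <- rep(FALSE, n)
  comps <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    queue <- i; seen[i] <- TRUE; members <- integer()
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      members <- c(members, v)
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(ids[members])
  }
  ord <- order(-vapply(comps, length, 0L), vapply(comps, `[[`, "", 1L))
  comps[ord]
}

#' Align variants on the union of their position labels
#'
#' @param variants list of [thf_variant()] objects.
#' @return character matrix, rows named by variant id, columns by position
#'   label in signature order; absences filled with `"-"`.
#' @export
signature_alignment <- function(variants) {
  stopifnot(length(variants) >= 1L)
  ids <- vapply(variants, function(v) v$id, "")
  cols <- sort_position_labels(
    Reduce(union, lapply(variants, function(v) names(v$residues))))
  m <- t(vapply(variants,
                function(v) vapply(cols, residue_at, "", variant = v),
                character(length(cols))))
  dimnames(m) <- list(ids, cols)
  m
}

#' Consensus sequence of an alignment
#'
#' Per column: if one symbol reaches the conservation `threshold`
#' (inclusive) it is emitted; otherwise the smallest IUPAC degenerate code
#' among R (A/G), Y (C/U), W (A/U) covering every base whose frequency is at
#' least `minor_floor` is emitted, falling back to `N`. Columns where gaps
#' are the majority emit `"-"`; otherwise frequencies are taken over
#' non-gap residues. Idempotent: the consensus of a consensus is itself.
#'
#' @param x a [signature_alignment()] matrix, a list of [thf_variant()]
#'   objects, or a character vector of equal-length sequence strings.
#' @param threshold conservation threshold (default 0.75, inclusive).
#' @param minor_floor minimum frequency for a base to enter a degenerate
#'   code (default 0.10).
#' @return single consensus string with per-column vector in
#'   `attr(, "per_column")`.
#' @export
consensus <- function(x, threshold = 0.75, minor_floor = 0.10) {
  if (is.character(x) && is.null(dim(x))) {
    chars <- strsplit(x, "")
    if (length(unique(lengths(chars))) != 1L)
      stop("sequences must have equal length")
    x <- do.call(rbind, chars)
  } else if (!is.matrix(x)) {
    x <- signature_alignment(x)
  }
  per_col <- apply(x, 2L, function(col) {
    if (mean(col == GAP) > 0.5) return(GAP)
    obs <- col[col != GAP]
    freq <- table(obs) / length(obs)
    if (max(freq) >= threshold) return(names(freq)[which.max(freq)])
    kept <- names(freq)[freq >= minor_floor]
    codes <- list(R = c("A", "G"), Y = c("C", "U"), W = c("A", "U"))
    for (code in names(codes)) if (all(kept %in% codes[[code]])) return(code)
    "N"
  })
  structure(paste(per_col, collapse = ""), per_column = per_col)
}

#' Write variant signatures to FASTA
#'
#' Headers carry the metadata as key=value tokens, e.g.
#' `>980 stem=11 source=natural cols=1,2,...,23`; deletions are written as
#' `-` in the sequence so every record has one character per column label.
#'
#' @param variants list of [thf_variant()] objects.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_signature_fasta <- function(variants, file) {
  names <- vapply(variants, function(v)
    sprintf("%s stem=%d source=%s cols=%s", v$id, v$stem_length_bp, v$source,
            paste(names(v$residues), collapse = ",")), "")
  seqs <- lapply(variants, function(v) unname(v$residues))
  seqinr::write.fasta(sequences = seqs, names = names, file.out = file,
                      nbchar = 80)
  invisible(file)
}

#' Read variant signatures from FASTA
#'
#' Inverse of [write_signature_fasta()]. When a header lacks a `cols=`
#' token, a 23-character record is assigned labels "1".."23".
#'
#' @param file FASTA path.
#' @return list of [thf_variant()] objects.
#' @export
read_signature_fasta <- function(file) {
  recs <- seqinr::read.fasta(file, as.string = FALSE, forceDNAtolower = FALSE)
  lapply(recs, function(rec) {
    annot <- sub("^>", "", attr(rec, "Annot"))
    tokens <- strsplit(annot, "\\s+")[[1L]]
    id <- tokens[[1L]]
    kv <- tokens[-1L][grepl("=", tokens[-1L], fixed = TRUE)]
    vals <- stats::setNames(sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
    seq <- toupper(as.character(rec))
    cols <- if ("cols" %in% names(vals)) {
      strsplit(vals[["cols"]], ",", fixed = TRUE)[[1L]]
    } else if (length(seq) == 23L) {
      as.character(1:23)
    } else {
      stop("record '", id, "': no cols= metadata and length != 23")
    }
    if (length(cols) != length(seq))
      stop("record '", id, "': cols metadata does not match sequence length")
    thf_variant(
      id = id,
      residues = stats::setNames(seq, cols),
      source = if (identical(vals[["source"]], "artificial")) "artificial" else "natural",
      stem_length_bp = if ("stem" %in% names(vals)) as.integer(vals[["stem"]]) else NULL
    )
  })
}

#' Per-variant signature report
#'
#' One row per variant: family index, G:C count and per-pair classes of the
#' long-range pairing, and point-mutation distance to a reference variant.
#'
#' @param variants list of [thf_variant()] objects.
#' @param reference id of the reference variant (default `"4LVV"`); `NA`
#'   distances if absent.
#' @param max_distance family edge threshold passed to [family_components()].
#' @return data.frame.
#' @export
signature_report <- function(variants, reference = "4LVV", max_distance = 2) {
  ids <- vapply(variants, function(v) v$id, "")
  fams <- family_components(variants, max_distance = max_distance)
  fam_of <- stats::setNames(rep(seq_along(fams), lengths(fams)), unlist(fams))
  ref <- variants[ids == reference]
  prof <- lapply(variants, pairing_profile)
  pair_classes <- t(vapply(prof, function(p) p$pairs$class, character(5L)))
  colnames(pair_classes) <- paste0("pair_", LOOP_RECEPTOR_PAIRS$loop_pos, "_",
                                   LOOP_RECEPTOR_PAIRS$receptor_pos)
  data.frame(
    id = ids,
    source = vapply(variants, function(v) v$source, ""),
    stem_length_bp = vapply(variants, function(v) v$stem_length_bp, 0L),
    family = unname(fam_of[ids]),
    gc_count = vapply(prof, function(p) p$gc_count, 0L),
    pair_classes,
    dist_to_reference = if (length(ref)) {
      vapply(variants, point_mutation_distance, 0L, b = ref[[1L]])
    } else NA_integer_,
    stringsAsFactors = FALSE
  )
}
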