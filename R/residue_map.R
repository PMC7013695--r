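#' Ballesteros-Weinstein residue map
#'
#' Class A GPCR positions are written `h.p`: helix `h` (1-7) and position `p`
#' relative to the helix's most conserved residue, which is defined as `x.50`.
#' A `bw_map` stores one anchor residue id per helix plus the helix spans used
#' to validate lookups, so metrics can be requested as "6.48", "3.50" etc.
#' regardless of author numbering.
#'
#' @param anchors named numeric vector of length 7: residue id of the x.50
#'   position of each helix, names `"1"`..`"7"` (any order, all required).
#' @param chain receptor chain identifier the anchors refer to.
#' @param spans optional 7 x 2 matrix (rows = helices 1-7) of first/last
#'   residue ids; defaults to anchor +/- 25.
#' @return object of class `bw_map`.
#' @export
bw_map <- function(anchors, chain = "R", spans = NULL) {
  anchors <- anchors[order(as.integer(names(anchors)))]
  if (length(anchors) != 7L || !identical(names(anchors), as.character(1:7)))
    smd_stop("anchors must be a named vector covering helices 1..7", "switchmd_mapping_error")
  if (is.null(spans)) {
    spans <- cbind(first = anchors - 25L, last = anchors + 25L)
  }
  spans <- as.matrix(spans)
  if (!all(spans[, 1] <= anchors & anchors <= spans[, 2]))
    smd_stop("every anchor must lie inside its helix span", "switchmd_mapping_error")
  structure(list(anchors = anchors, chain = chain, spans = spans), class = "bw_map")
}

#' @export
print.bw_map <- function(x, ...) {
  cat("bw_map: chain", x$chain, "\n")
  for (h in 1:7)
    cat(sprintf("  TM%d  %d.50 = %d   span %d..%d\n", h, h,
                x$anchors[[h]], x$spans[h, 1], x$spans[h, 2]))
  invisible(x)
}

#' Resolve a Ballesteros-Weinstein label to a residue
#'
#' Within a helix, position `p` maps to `anchor + (p - 50)`. Labels resolving
#' outside the helix span raise a mapping error naming the span.
#'
#' @param map a [bw_map()].
#' @param label text like `"6.48"`.
#' @return list with `chain` and `resno`.
#' @export
resolve_bw <- function(map, label) {
  m <- regmatches(label, regexec("^([1-7])\\.([0-9]{1,2})$", label))[[1]]
  if (length(m) != 3L)
    smd_stop(sprintf("'%s' is not a valid h.p label (h in 1..7)", label), "switchmd_mapping_error")
  h <- as.integer(m[2]); p <- as.integer(m[3])
  resno <- map$anchors[[h]] + (p - 50L)
  if (resno < map$spans[h, 1] || resno > map$spans[h, 2])
    smd_stop(sprintf("%s resolves to residue %d outside TM%d span %d..%d",
                     label, resno, h, map$spans[h, 1], map$spans[h, 2]),
             "switchmd_mapping_error")
  list(chain = map$chain, resno = as.integer(resno))
}

#' Label a residue id with its Ballesteros-Weinstein position
#' @param map a [bw_map()].
#' @param resno residue id.
#' @return label text, or `NA` if the residue lies in no helix span.
#' @export
bw_label_of <- function(map, resno) {
  for (h in 1:7) {
    if (resno >= map$spans[h, 1] && resno <= map$spans[h, 2]) {
      p <- 50L + (resno - map$anchors[[h]])
      return(sprintf("%d.%d", h, p))
    }
  }
  NA_character_
}

#' Detect conserved class A motifs and propose x.50 anchors
#'
#' Scans a one-letter sequence for the DRY (TM3), CWxP (TM6) and NPxxY (TM7)
#' motifs and returns the x.50 anchor each hit implies: the DRY arginine is
#' 3.50; the CWxP tryptophan is 6.48, so the 6.50 anchor sits two residues
#' after it; the NPxxY tyrosine is 7.53, so 7.50 sits three residues before
#' it. Positions are 1-based offsets into `sequence` unless `resno` supplies
#' the residue ids. Multiple hits of one motif are all returned, ranked by
#' how many of the other motifs co-occur in the sequence.
#'
#' @param sequence one-letter amino-acid string.
#' @param resno optional residue ids aligned with the sequence characters.
#' @return data frame with columns `motif`, `helix`, `anchor_resno`,
#'   `motif_start`, `rank` (possibly zero rows).
#' @export
detect_motifs <- function(sequence, resno = NULL) {
  s <- toupper(sequence)
  if (is.null(resno)) resno <- seq_len(nchar(s))
  hits <- list(
    list(motif = "DRY",   helix = 3L, pattern = "DRY",   anchor_off = 1L),
    list(motif = "CWxP",  helix = 6L, pattern = "CW.P",  anchor_off = 3L),
    list(motif = "NPxxY", helix = 7L, pattern = "NP..Y", anchor_off = 1L))
  rows <- list()
  found <- character()
  for (hdef in hits) {
    mm <- gregexpr(hdef$pattern, s)[[1]]
    if (mm[1] == -1L) next
    found <- c(found, hdef$motif)
    for (st in as.integer(mm)) {
      rows[[length(rows) + 1L]] <- data.frame(
        motif = hdef$motif, helix = hdef$helix,
        anchor_resno = resno[st + hdef$anchor_off],
        motif_start = resno[st])
    }
  }
  if (length(rows) == 0L)
    return(data.frame(motif = character(), helix = integer(),
                      anchor_resno = integer(), motif_start = integer(),
                      rank = integer()))
  out <- do.call(rbind, rows)
  out$rank <- length(found)   # co-occurrence support shared by all hits
  out[order(out$helix, out$motif_start), , drop = FALSE]
}

#' Read / write a residue-mapping config
#'
#' YAML with keys: `receptor_chain`, `ga_chain`, `anchors` (map helix ->
#' residue id), optional `spans` (map helix -> [first, last]), optional
#' `special` (named residues without BW labels, e.g. ICL3 `R233`, and the
#' G-alpha probe residues).
#'
#' @param path config file path.
#' @return list with `map` (a [bw_map()]) and `special` (named list).
#' @export
read_map_config <- function(path) {
  if (!file.exists(path)) smd_stop(sprintf("config not found: %s", path), "switchmd_io_error")
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$anchors) || length(cfg$anchors) != 7L)
    smd_stop("config must list all 7 helix anchors", "switchmd_mapping_error")
  anchors <- unlist(cfg$anchors)
  names(anchors) <- sub("^TM", "", names(anchors))
  spans <- NULL
  if (!is.null(cfg$spans)) {
    spans <- t(vapply(as.character(1:7), function(h) {
      sp <- cfg$spans[[h]]
      if (is.null(sp)) sp <- c(anchors[[h]] - 25L, anchors[[h]] + 25L)
      as.numeric(sp)
    }, numeric(2)))
    colnames(spans) <- c("first", "last")
  }
  list(map = bw_map(anchors, chain = cfg$receptor_chain %||% "R", spans = spans),
       ga_chain = cfg$ga_chain %||% "G",
       special = cfg$special %||% list())
}

#' @rdname read_map_config
#' @param map a [bw_map()].
#' @param ga_chain G-alpha chain id.
#' @param special named list of special residues.
#' @export
write_map_config <- function(map, path, ga_chain = "G", special = list()) {
  cfg <- list(receptor_chain = map$chain, ga_chain = ga_chain,
              anchors = as.list(setNames(as.integer(map$anchors), names(map$anchors))),
              spans = setNames(lapply(1:7, function(h) as.integer(map$spans[h, ])),
                               as.character(1:7)),
              special = special)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
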