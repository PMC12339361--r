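#' Build a barcode lookup index
#'
#' Indexes the first `read_length` bases of every detection sequence for
#' exact and single-mismatch lookup. The read length equals the number of
#' sequencing cycles actually imaged, so a 20-nt barcode read over 6
#' cycles is matched on its 6-base prefix. Prefixes shared by several
#' guides form intrinsically ambiguous collision groups: a read landing
#' on one can never be assigned to a single guide.
#'
#' @param lib A [barcode_library()].
#' @param read_length Number of leading detection-sequence bases indexed
#'   (`1 <= read_length <=` spacer length).
#' @return A `barcode_index`.
#' @export
build_index <- function(lib, read_length) {
  stopifnot(inherits(lib, "barcode_library"))
  read_length <- as.integer(read_length)
  if (read_length < 1L) stop("read_length must be >= 1", call. = FALSE)
  L <- nchar(lib$detect_seq[1])
  if (read_length > L) {
    stop("read_length exceeds detection sequence length (", L, ")",
         call. = FALSE)
  }
  prefix <- substr(lib$detect_seq, 1L, read_length)
  map <- new.env(parent = emptyenv(), size = nrow(lib) * 2L)
  for (i in seq_len(nrow(lib))) {
    key <- prefix[i]
    map[[key]] <- c(map[[key]], i)
  }
  collided <- prefix[duplicated(prefix)]
  structure(list(map = map, lib = lib, read_length = read_length,
                 prefix = prefix,
                 collision_groups = unique(collided)),
            class = "barcode_index")
}

#' @export
print.barcode_index <- function(x, ...) {
  cat(sprintf("<barcode_index: %d guides, read length %d, %d prefix collision group%s>\n",
              nrow(x$lib), x$read_length, length(x$collision_groups),
              if (length(x$collision_groups) == 1L) "" else "s"))
  invisible(x)
}

#' Match one called sequence against the barcode dictionary
#'
#' A read is `exact` when it equals the indexed prefix of exactly one
#' guide, `corrected` when it is Hamming distance 1 from exactly one
#' guide (and matches none exactly), `ambiguous` when several guides lie
#' within its distance tier, and `unmatched` otherwise. Exact hits take
#' priority over distance-1 hits; `N` counts as a mismatch at its
#' position.
#'
#' @param seq Character scalar over A/C/G/T/N of length
#'   `index$read_length`.
#' @param index A [build_index()] result.
#' @return One-row tibble: `sequence`, `status`, `guide_id`, `gene`,
#'   `hamming_distance` (`NA` unless exact/corrected).
#' @export
match_sequence <- function(seq, index) {
  stopifnot(inherits(index, "barcode_index"))
  if (nchar(seq) != index$read_length) {
    stop("query length ", nchar(seq), " != read length ", index$read_length,
         call. = FALSE)
  }
  hit <- match_one(seq, index)
  tibble::tibble(sequence = seq, status = hit$status,
                 guide_id = hit$guide_id, gene = hit$gene,
                 hamming_distance = hit$distance)
}

match_one <- function(seq, index) {
  lib <- index$lib
  nohit <- list(status = "unmatched", guide_id = NA_character_,
                gene = NA_character_, distance = NA_integer_)
  exact <- index$map[[seq]]
  if (!is.null(exact)) {
    if (length(exact) > 1L || lib$duplicate[exact[1]]) {
      nohit$status <- "ambiguous"
      nohit$distance <- 0L
      return(nohit)
    }
    return(list(status = "exact", guide_id = lib$guide_id[exact],
                gene = lib$gene[exact], distance = 0L))
  }
  # enumerate the 3L Hamming-1 neighbours
  hits <- integer(0)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (pos in seq_along(chars)) {
    orig <- chars[pos]
    for (b in c("A", "C", "G", "T")) {
      if (b == orig) next
      chars[pos] <- b
      cand <- index$map[[paste(chars, collapse = "")]]
      if (!is.null(cand)) hits <- c(hits, cand)
    }
    chars[pos] <- orig
  }
  hits <- unique(hits)
  if (length(hits) == 0L) return(nohit)
  if (length(hits) > 1L || any(lib$duplicate[hits])) {
    nohit$status <- "ambiguous"
    nohit$distance <- 1L
    return(nohit)
  }
  list(status = "corrected", guide_id = lib$guide_id[hits],
       gene = lib$gene[hits], distance = 1L)
}

#' Match a table of called spot sequences
#'
#' Vectorised [match_sequence()] over the `sequence` column of a spot
#' table; identical sequences are looked up once.
#'
#' @param spots Tibble with a `sequence` column (e.g. from
#'   [call_bases()]).
#' @param index A [build_index()] result.
#' @return `spots` with `status`, `guide_id`, `gene` and
#'   `hamming_distance` columns appended.
#' @export
match_spots <- function(spots, index) {
  if (nrow(spots) == 0L) {
    return(dplyr::mutate(spots, status = character(),
                         guide_id = character(), gene = character(),
                         hamming_distance = integer()))
  }
  uq <- unique(spots$sequence)
  res <- lapply(uq, function(s) {
    h <- match_one(s, index)
    tibble::tibble(sequence = s, status = h$status, guide_id = h$guide_id,
                   gene = h$gene, hamming_distance = h$distance)
  })
  dplyr::left_join(spots, dplyr::bind_rows(res), by = "sequence")
}
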