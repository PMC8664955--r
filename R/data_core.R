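ALPHABET <- c("A", "C", "G", "U", "N")
PAD <- "-"

#' Nucleotide sequence with an explicit reading orientation
#'
#' Sequences are stored exactly as read; `T` and `U` are distinct letters in
#' IO but one pairing class everywhere downstream. The pad sentinel `-` is
#' produced only by [pad_sequence()] and encodes to an all-zero row.
#'
#' @param letters Character scalar over `A,C,G,U,T,N` (and `-` for pads).
#' @param orientation `"five_to_three"` (miRNA convention) or
#'   `"three_to_five"` (target convention).
#' @return An object of class `nt_sequence`.
#' @export
nt_sequence <- function(letters,
                        orientation = c("five_to_three", "three_to_five")) {
  orientation <- match.arg(orientation)
  stopifnot(is.character(letters), length(letters) == 1L)
  if (nchar(letters) == 0L) stop("sequence must be non-empty")
  check_letters(letters, allow_pad = TRUE)
  structure(list(letters = toupper(letters), orientation = orientation),
            class = "nt_sequence")
}

check_letters <- function(x, allow_pad = FALSE, line = NULL) {
  ok <- c("A", "C", "G", "U", "T", "N", if (allow_pad) PAD)
  ch <- strsplit(toupper(x), "")[[1]]
  bad <- setdiff(unique(ch), ok)
  if (length(bad)) {
    where <- if (is.null(line)) "" else sprintf(" at line %d", line)
    stop(sprintf("illegal letter '%s' in sequence%s", bad[[1]], where),
         call. = FALSE)
  }
  invisible(x)
}

seq_letters <- function(x) if (inherits(x, "nt_sequence")) x$letters else x

#' @export
print.nt_sequence <- function(x, ...) {
  cat(sprintf("<nt_sequence %s, %d nt> %s\n", x$orientation,
              nchar(x$letters), x$letters))
  invisible(x)
}

#' A miRNA plus one candidate target site with a binary label
#'
#' The analysis unit: the miRNA is written 5'->3', the target site 3'->5',
#' so that equal string offsets face each other in the duplex.
#'
#' @param pair_id Identifier string.
#' @param mirna,target Sequences (strings or [nt_sequence()]).
#' @param label `"positive"` or `"negative"`.
#' @return An object of class `mirtar_pair`.
#' @export
mirtar_pair <- function(pair_id, mirna, target,
                        label = c("positive", "negative")) {
  label <- match.arg(label)
  mirna <- seq_letters(mirna); target <- seq_letters(target)
  check_letters(mirna); check_letters(target)
  structure(list(pair_id = as.character(pair_id),
                 mirna = nt_sequence(mirna, "five_to_three"),
                 target = nt_sequence(target, "three_to_five"),
                 label = label),
            class = "mirtar_pair")
}

#' Padding geometry of a dataset family
#'
#' Two built-ins mirror the geometries of the published dataset families:
#' `"deepmirtar"` pads targets of variable length to 53 nt, `"miraw"` uses
#' fixed 40-nt sites (a 30-nt site extended 5 nt per side). miRNAs are padded
#' to 26 nt in both.
#'
#' @param name `"deepmirtar"`, `"miraw"`, or any name when the pad lengths
#'   are given explicitly.
#' @param mirna_pad_len,target_pad_len Pad lengths in nucleotides; filled in
#'   automatically for the two built-ins.
#' @return An object of class `dataset_profile`.
#' @examples
#' dataset_profile("deepmirtar")
#' @export
dataset_profile <- function(name = "deepmirtar", mirna_pad_len = NULL,
                            target_pad_len = NULL) {
  if (is.null(mirna_pad_len) || is.null(target_pad_len)) {
    builtin <- switch(name,
      deepmirtar = c(26L, 53L),
      miraw = c(26L, 40L),
      stop(sprintf("unknown profile '%s'; give pad lengths explicitly", name)))
    mirna_pad_len <- builtin[[1]]; target_pad_len <- builtin[[2]]
  }
  stopifnot(mirna_pad_len >= 1, target_pad_len >= 1)
  structure(list(name = name,
                 mirna_pad_len = as.integer(mirna_pad_len),
                 target_pad_len = as.integer(target_pad_len)),
            class = "dataset_profile")
}

#' @export
print.dataset_profile <- function(x, ...) {
  cat(sprintf("<dataset_profile '%s': miRNA pad %d nt, target pad %d nt>\n",
              x$name, x$mirna_pad_len, x$target_pad_len))
  invisible(x)
}

#' Parse and build L/LT position labels
#'
#' Positions are 1-based on two tracks: `L<i>` on the miRNA (5'->3') and
#' `LT<j>` on the target (3'->5').
#'
#' @param labels Character vector like `c("L7", "LT9")`.
#' @return `parse_positions()`: data.frame with `track` ("L"/"LT") and
#'   `index`; `position_label()`: the string form.
#' @export
parse_positions <- function(labels) {
  m <- regmatches(labels, regexec("^(LT|L)([0-9]+)$", labels))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop(sprintf("malformed position label '%s'", labels[bad][[1]]))
  data.frame(track = vapply(m, `[[`, "", 2L),
             index = as.integer(vapply(m, `[[`, "", 3L)),
             stringsAsFactors = FALSE)
}

#' @rdname parse_positions
#' @param track `"L"` or `"LT"`.
#' @param index 1-based position index (vectorised).
#' @export
position_label <- function(track, index) paste0(track, index)

#' Positions of a contiguous region
#'
#' @param track `"L"` or `"LT"`.
#' @param start 1-based start index.
#' @param len Region length in nt.
#' @return Character vector of position labels.
#' @examples
#' region_positions("L", 2, 6) # the seed region L2-L7
#' @export
region_positions <- function(track, start, len) {
  position_label(track, seq.int(start, start + len - 1L))
}

#' The named regions used throughout the analyses
#'
#' `seed2-6` is the 6-nt seed L2-L7 (the label follows the figure naming
#' convention of the field and is naming only); the remaining four are the
#' feature regions recurrently examined: `L4-4`, `L13-4`, `L10-4`, `LT7-5`.
#'
#' @return Named list of position-label vectors.
#' @export
builtin_regions <- function() {
  list(`seed2-6` = region_positions("L", 2, 6),
       `L4-4`   = region_positions("L", 4, 4),
       `L13-4`  = region_positions("L", 13, 4),
       `L10-4`  = region_positions("L", 10, 4),
       `LT7-5`  = region_positions("LT", 7, 5))
}

#' Read named regions from a YAML file
#'
#' Each entry maps a region label to `track`, `start`, `len`. The package
#' ships the five standard regions in
#' `system.file("extdata", "regions.yaml", package = "mirtarprobe")`.
#'
#' @param path YAML file; defaults to the shipped regions.
#' @return Named list of position-label vectors, as [builtin_regions()].
#' @export
read_regions_yaml <- function(path = system.file("extdata", "regions.yaml",
                                                 package = "mirtarprobe")) {
  y <- yaml::read_yaml(path)
  lapply(y, function(r) region_positions(r$track, r$start, r$len))
}

#' Map a position label to its row in the concatenated encoding
#'
#' Rows 1..mirna_pad_len hold the miRNA track, the remaining rows the target
#' track, so `L,i -> i` and `LT,j -> mirna_pad_len + j`.
#'
#' @param labels Character vector of position labels.
#' @param profile A [dataset_profile()].
#' @return Integer row indices (1-based).
#' @export
position_to_row <- function(labels, profile) {
  p <- parse_positions(labels)
  lim <- ifelse(p$track == "L", profile$mirna_pad_len, profile$target_pad_len)
  bad <- p$index < 1L | p$index > lim
  if (any(bad))
    stop(sprintf("position %s out of bounds for profile '%s'",
                 labels[bad][[1]], profile$name))
  ifelse(p$track == "L", p$index, profile$mirna_pad_len + p$index)
}

#' Pad a sequence to a fixed length
#'
#' Pads are appended at the 3'-most end of the written order with the `-`
#' sentinel, which encodes to an all-zero row, so the L/LT indices of real
#' nucleotides are stable across pairs.
#'
#' @param seq String or [nt_sequence()].
#' @param length Target length (nt).
#' @return Padded sequence string.
#' @export
pad_sequence <- function(seq, length) {
  s <- seq_letters(seq)
  n <- nchar(s)
  if (n > length)
    stop(sprintf("sequence of length %d exceeds pad length %d", n, length))
  paste0(s, strrep(PAD, length - n))
}

letter_onehot <- function(letter) {
  v <- numeric(5L)
  if (letter == PAD) return(v)
  l <- if (letter == "T") "U" else letter
  v[match(l, ALPHABET)] <- 1
  v
}

encode_letters <- function(s, len) {
  s <- pad_sequence(s, len)
  ch <- strsplit(toupper(s), "")[[1]]
  t(vapply(ch, letter_onehot, numeric(5L)))
}

#' One-hot encode a miRNA:target pair
#'
#' Rows 1..mirna_pad_len are the miRNA written 5'->3'; the remaining rows the
#' target written 3'->5'. Columns follow the alphabet `A,C,G,U,N`; `T`
#' encodes to the `U` column (one pairing class), `N` to its own column, and
#' pad positions to all-zero rows.
#'
#' @param mirna,target Sequence strings (or a [mirtar_pair()] as `mirna`).
#' @param profile A [dataset_profile()].
#' @return Numeric matrix of `mirna_pad_len + target_pad_len` rows by 5
#'   columns, with the profile attached as attribute `"profile"`.
#' @examples
#' enc <- encode_pair("ACGUACGU", "UGCAUGCA", dataset_profile("deepmirtar"))
#' nrow(enc) # 79
#' @export
encode_pair <- function(mirna, target = NULL, profile = dataset_profile()) {
  if (inherits(mirna, "mirtar_pair")) {
    target <- mirna$target$letters
    mirna <- mirna$mirna$letters
  }
  m <- encode_letters(seq_letters(mirna), profile$mirna_pad_len)
  t_ <- encode_letters(seq_letters(target), profile$target_pad_len)
  enc <- rbind(m, t_)
  dimnames(enc) <- list(NULL, ALPHABET)
  attr(enc, "profile") <- profile
  enc
}

#' Decode an encoded input back to letter strings
#'
#' Inverse of [encode_pair()] up to the T/U synonym (both decode to `U`);
#' all-zero rows decode to the pad sentinel and are trimmed.
#'
#' @param enc Matrix from [encode_pair()].
#' @param profile A [dataset_profile()]; defaults to the one attached to `enc`.
#' @return List with `mirna` and `target` strings.
#' @export
decode_pair <- function(enc, profile = attr(enc, "profile")) {
  letters_of <- function(rows) {
    ch <- apply(rows, 1L, function(r) {
      if (all(r == 0)) PAD else ALPHABET[which.max(r)]
    })
    sub("-+$", "", paste(ch, collapse = ""))
  }
  list(mirna = letters_of(enc[seq_len(profile$mirna_pad_len), , drop = FALSE]),
       target = letters_of(enc[-seq_len(profile$mirna_pad_len), , drop = FALSE]))
}

#' Encode a pair table into a 3-D array
#'
#' @param pairs Pair table (data.frame with `mirna_seq`, `target_seq`).
#' @param profile A [dataset_profile()].
#' @return Array `rows x 5 x n_pairs`.
#' @export
encode_table <- function(pairs, profile = dataset_profile()) {
  n <- nrow(pairs)
  rows <- profile$mirna_pad_len + profile$target_pad_len
  arr <- array(0, dim = c(rows, 5L, n),
               dimnames = list(NULL, ALPHABET, NULL))
  for (i in seq_len(n))
    arr[, , i] <- encode_pair(pairs$mirna_seq[[i]], pairs$target_seq[[i]], profile)
  attr(arr, "profile") <- profile
  arr
}

#' Read and write pair tables
#'
#' The pair table is a TSV with header `pair_id, mirna_seq, target_seq,
#' label`; labels `1/positive` and `0/negative` are accepted on input and
#' written back as `positive`/`negative`.
#'
#' @param path File path.
#' @return Data.frame with the four columns, labels normalised.
#' @export
read_pair_table <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                   strip.white = TRUE)
  need <- c("pair_id", "mirna_seq", "target_seq", "label")
  if (!all(need %in% names(df)))
    stop(sprintf("pair table must have columns %s", paste(need, collapse = ", ")))
  df <- df[, need]
  for (i in seq_len(nrow(df))) {
    line <- i + 1L # header is line 1
    row <- df[i, ]
    if (any(is.na(row)) || any(row == ""))
      stop(sprintf("malformed row at line %d of %s", line, path))
    check_letters(row$mirna_seq, line = line)
    check_letters(row$target_seq, line = line)
  }
  df$mirna_seq <- toupper(df$mirna_seq)
  df$target_seq <- toupper(df$target_seq)
  df$label <- normalize_labels(df$label)
  df
}

normalize_labels <- function(x) {
  out <- ifelse(x %in% c("1", "positive", "pos", "TRUE"), "positive",
         ifelse(x %in% c("0", "negative", "neg", "FALSE"), "negative", NA))
  if (anyNA(out))
    stop(sprintf("unrecognised label '%s'", x[is.na(out)][[1]]))
  out
}

#' @rdname read_pair_table
#' @param pairs Pair table to write.
#' @export
write_pair_table <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read paired FASTA files into a pair table
#'
#' Record IDs join the miRNA and target files; every ID present in the miRNA
#' file must appear in the target file.
#'
#' @param mirna_fa,target_fa FASTA paths (miRNA written 5'->3', targets
#'   3'->5').
#' @param labels Named vector (by record ID) of labels, or a single label
#'   recycled to all records.
#' @return Pair table data.frame.
#' @export
read_pair_fasta <- function(mirna_fa, target_fa, labels = "positive") {
  mi <- read_fasta(mirna_fa)
  tg <- read_fasta(target_fa)
  miss <- setdiff(names(mi), names(tg))
  if (length(miss))
    stop(sprintf("record '%s' missing from target FASTA", miss[[1]]))
  ids <- names(mi)
  lab <- if (length(labels) == 1L && is.null(names(labels)))
    rep(labels, length(ids)) else labels[ids]
  data.frame(pair_id = ids, mirna_seq = toupper(unname(mi[ids])),
             target_seq = toupper(unname(tg[ids])),
             label = normalize_labels(unname(lab)),
             stringsAsFactors = FALSE)
}

read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop(sprintf("no FASTA records in %s", path))
  id <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(gsub("\\s", "", x), collapse = ""), "")
  setNames(seqs, id)
}
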