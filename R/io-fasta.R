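# FASTA reading/writing with strict residue validation. Biostrings does the
# parsing; the validation layer enforces the alphabets the pipeline relies on
# downstream (aligned protein FASTA is the MSA carrier, so '-' is legal in
# protein sequences; '.' gaps are normalized to '-').

.protein_alphabet <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                       "F","P","S","T","W","Y","V","X","-","?","*")
.dna_alphabet <- c("A","C","G","T","N")

.check_alphabet <- function(seq, id, alphabet) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% alphabet))
  if (length(bad) > 0L)
    stop("illegal residue '", chars[bad[1]], "' at position ", bad[1],
         " in sequence '", id, "'")
  invisible(TRUE)
}

#' Read a FASTA file into a table of sequence records
#'
#' @param path Path to a (plain or aligned) FASTA file.
#' @param moltype `"protein"` or `"dna"`; controls alphabet validation.
#'   Protein sequences may contain the 20 standard residues plus
#'   `X`, `-`, `?`, `*`; DNA sequences only `A,C,G,T,N`.
#' @return A data.frame with columns `id`, `desc`, `seq` (one row per
#'   record, file order preserved, gaps retained) and attribute `moltype`.
#' @export
read_fasta <- function(path, moltype = c("protein", "dna")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("FASTA record with empty id")
  if (anyDuplicated(ids))
    stop("duplicate sequence id: '", ids[duplicated(ids)][1], "'")
  seqs <- toupper(as.character(set))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for id '", ids[nchar(seqs) == 0L][1], "'")
  alphabet <- if (moltype == "protein") .protein_alphabet else .dna_alphabet
  for (i in seq_along(ids)) .check_alphabet(seqs[i], ids[i], alphabet)
  out <- data.frame(id = ids, desc = desc, seq = unname(seqs),
                    stringsAsFactors = FALSE)
  attr(out, "moltype") <- moltype
  out
}

#' Write sequence records to FASTA
#'
#' @param x A data.frame with columns `id`, `seq` (and optionally `desc`),
#'   or a named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x)) {
    if (is.null(names(x))) stop("sequence vector must be named")
    x <- data.frame(id = names(x), desc = "", seq = unname(x),
                    stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "seq") %in% names(x)))
  if (anyDuplicated(x$id)) stop("duplicate sequence id: '",
                                x$id[duplicated(x$id)][1], "'")
  headers <- x$id
  if (!is.null(x$desc)) {
    has_desc <- !is.na(x$desc) & nzchar(x$desc)
    headers[has_desc] <- paste(x$id[has_desc], x$desc[has_desc])
  }
  set <- Biostrings::BStringSet(setNames(x$seq, headers))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# Named character vector of sequences from a read_fasta() table.
seq_vector <- function(records) setNames(records$seq, records$id)
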