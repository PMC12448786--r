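#' Construct a document record
#'
#' A document is the unit of the corpus: bibliographic metadata plus an
#' abstract and/or a full text. At least one of `abstract` and `full_text`
#' must be non-empty.
#'
#' @param doc_id Unique opaque identifier.
#' @param title Document title (non-empty).
#' @param abstract Abstract text; may be empty.
#' @param full_text Full body text; may be empty.
#' @param year Publication year or `NA`.
#' @param keywords Character vector of author keywords.
#' @param cited_doc_ids Identifiers of documents this one cites.
#' @return An object of class `"lr_document"`.
#' @export
document <- function(doc_id, title, abstract = "", full_text = "",
                     year = NA_integer_, keywords = character(),
                     cited_doc_ids = character()) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id))
  if (!is.character(title) || length(title) != 1L || !nzchar(trimws(title))) {
    stop("document '", doc_id, "': title must be a non-empty string")
  }
  abstract <- as.character(abstract %||% "")
  full_text <- as.character(full_text %||% "")
  if (!nzchar(abstract) && !nzchar(full_text)) {
    stop("document '", doc_id, "': abstract and full_text cannot both be empty")
  }
  structure(
    list(
      doc_id = doc_id, title = title, abstract = abstract,
      full_text = full_text,
      year = if (is.null(year) || is.na(year)) NA_integer_ else as.integer(year),
      keywords = as.character(keywords %||% character()),
      cited_doc_ids = as.character(cited_doc_ids %||% character())
    ),
    class = "lr_document"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a corpus index from documents
#'
#' @param documents List of [document()] objects.
#' @return A `"corpus_index"`: documents keyed by id, an (initially empty)
#'   chunk table, and a level -> chunk-id map.
#' @export
corpus_index <- function(documents) {
  ids <- vapply(documents, function(d) d$doc_id, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate doc_id in corpus: ", paste(unique(dup), collapse = ", "))
  }
  names(documents) <- ids
  structure(
    list(
      documents = documents,
      chunks = list(),
      by_level = list(abstract = character(), fulltext = character())
    ),
    class = "corpus_index"
  )
}

#' @export
print.corpus_index <- function(x, ...) {
  cat("<corpus_index> ", length(x$documents), " documents, ",
      length(x$chunks), " chunks (",
      length(x$by_level$abstract), " abstract, ",
      length(x$by_level$fulltext), " fulltext)\n", sep = "")
  invisible(x)
}

#' Load a corpus from JSON Lines records
#'
#' Reads one JSON object per line with the [document()] fields. When
#' `texts_dir` is given, a file `<doc_id>.md` (or `.txt`) found there replaces
#' the record's `full_text`; markdown formatting marks are stripped.
#'
#' @param records_path Path to a JSON Lines file of document records.
#' @param texts_dir Optional directory of per-document text files.
#' @return A [corpus_index()] with all documents and no chunks.
#' @export
load_corpus <- function(records_path, texts_dir = NULL) {
  if (!file.exists(records_path)) {
    stop("cannot read document records: ", records_path)
  }
  lines <- readLines(records_path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  docs <- lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    full_text <- rec$full_text %||% ""
    if (!is.null(texts_dir)) {
      for (ext in c(".md", ".txt")) {
        p <- file.path(texts_dir, paste0(rec$doc_id, ext))
        if (file.exists(p)) {
          full_text <- strip_markdown(paste(
            readLines(p, encoding = "UTF-8", warn = FALSE), collapse = "\n"))
          break
        }
      }
    }
    document(
      doc_id = rec$doc_id, title = rec$title,
      abstract = rec$abstract %||% "", full_text = full_text,
      year = rec$year %||% NA_integer_,
      keywords = unlist(rec$keywords) %||% character(),
      cited_doc_ids = unlist(rec$cited_doc_ids) %||% character()
    )
  })
  corpus_index(docs)
}

# Markdown is ingested as plain text: headings, emphasis and link syntax are
# dropped, structure is not interpreted.
strip_markdown <- function(x) {
  x <- gsub("(?m)^#{1,6}[ \t]*", "", x, perl = TRUE)
  x <- gsub("\\[([^]]*)\\]\\([^)]*\\)", "\\1", x, perl = TRUE)
  x <- gsub("[*_`]+", "", x)
  x
}

default_separators <- function() c("\n\n", "\n", ". ", "! ", "? ", " ", "")

#' Split corpus documents into retrieval chunks
#'
#' Each non-empty abstract becomes exactly one abstract-level chunk regardless
#' of its length. Each full text is segmented into fulltext-level chunks of at
#' most `chunk_size` characters with `overlap` characters carried over between
#' consecutive chunks, splitting preferentially at the earliest separator in
#' the hierarchy that permits a boundary (paragraph break, line break,
#' sentence end, space), falling back to a hard character cut.
#'
#' @param index A [corpus_index()].
#' @param chunk_size Maximum chunk length in characters (default 500).
#' @param overlap Characters of carry-over between consecutive chunks
#'   (default 100); must satisfy `0 <= overlap < chunk_size`.
#' @param separators Ordered split-string hierarchy; the last entry must be
#'   `""` (character-level fallback).
#' @return The index with `chunks` and `by_level` populated. Chunk ids are
#'   `<doc_id>#<level><ordinal>` so they are stable and human-readable.
#' @export
chunk_corpus <- function(index, chunk_size = 500, overlap = 100,
                         separators = default_separators()) {
  stopifnot(inherits(index, "corpus_index"))
  if (!(overlap >= 0 && overlap < chunk_size)) {
    stop("invalid chunking configuration: need 0 <= overlap < chunk_size")
  }
  if (!length(separators) || separators[[length(separators)]] != "") {
    stop("separators must be non-empty and end with \"\" (character fallback)")
  }
  chunks <- list()
  by_level <- list(abstract = character(), fulltext = character())
  for (doc in index$documents) {
    if (nzchar(doc$abstract)) {
      cid <- paste0(doc$doc_id, "#abstract1")
      chunks[[cid]] <- chunk_record(cid, doc$doc_id, "abstract",
                                    doc$abstract, 0L, nchar(doc$abstract))
      by_level$abstract <- c(by_level$abstract, cid)
    }
    if (nzchar(doc$full_text)) {
      spans <- split_text(doc$full_text, chunk_size, overlap, separators)
      for (i in seq_len(nrow(spans))) {
        cid <- paste0(doc$doc_id, "#fulltext", i)
        chunks[[cid]] <- chunk_record(
          cid, doc$doc_id, "fulltext",
          substr(doc$full_text, spans$start[i] + 1L, spans$end[i]),
          spans$start[i], spans$end[i])
        by_level$fulltext <- c(by_level$fulltext, cid)
      }
    }
  }
  index$chunks <- chunks
  index$by_level <- by_level
  index
}

chunk_record <- function(chunk_id, doc_id, level, text, char_start, char_end) {
  structure(
    list(chunk_id = chunk_id, doc_id = doc_id, level = level, text = text,
         char_start = as.integer(char_start), char_end = as.integer(char_end)),
    class = "lr_chunk"
  )
}

#' Compute chunk spans for one text
#'
#' The splitter scans forward: for each window of `chunk_size` characters it
#' ends the chunk at the last occurrence of the highest-priority separator
#' that leaves more than `overlap` characters of new content (so the next
#' chunk makes progress); the empty-string fallback cuts at exactly
#' `chunk_size`. The next chunk starts `overlap` characters before the
#' previous end. Offsets are 0-based, end-exclusive.
#'
#' @param text Character scalar.
#' @inheritParams chunk_corpus
#' @return A data.frame with integer columns `start` and `end`.
#' @export
split_text <- function(text, chunk_size = 500, overlap = 100,
                       separators = default_separators()) {
  if (!(overlap >= 0 && overlap < chunk_size)) {
    stop("invalid chunking configuration: need 0 <= overlap < chunk_size")
  }
  n <- nchar(text)
  if (n == 0L) return(data.frame(start = integer(), end = integer()))
  # precompute all occurrence end-positions (0-based, end-exclusive) per separator
  sep_ends <- lapply(separators, function(s) {
    if (!nzchar(s)) return(NULL)
    m <- gregexpr(s, text, fixed = TRUE)[[1]]
    if (m[1] == -1L) integer() else (as.integer(m) - 1L) + nchar(s)
  })
  starts <- integer()
  ends <- integer()
  pos <- 0L
  repeat {
    if (pos + chunk_size >= n) {
      starts <- c(starts, pos); ends <- c(ends, n)
      break
    }
    lo <- pos + overlap      # boundary must exceed this for forward progress
    hi <- pos + chunk_size
    cut <- NA_integer_
    for (se in sep_ends) {
      if (is.null(se)) { cut <- hi; break }  # "" fallback: hard cut
      ok <- se[se > lo & se <= hi]
      if (length(ok)) { cut <- max(ok); break }
    }
    starts <- c(starts, pos); ends <- c(ends, cut)
    pos <- cut - overlap
  }
  data.frame(start = starts, end = ends)
}

#' Serialize chunks to JSON Lines
#'
#' @param index A chunked [corpus_index()].
#' @param path Output file.
#' @export
write_chunks <- function(index, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (ch in index$chunks) {
    writeLines(jsonlite::toJSON(unclass(ch), auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Re-load chunks serialized by [write_chunks()] into an index
#'
#' @param index A [corpus_index()] holding the parent documents.
#' @param path JSON Lines file of chunk records.
#' @export
read_chunks <- function(index, path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  chunks <- list()
  by_level <- list(abstract = character(), fulltext = character())
  for (ln in lines[nzchar(lines)]) {
    rec <- jsonlite::fromJSON(ln)
    if (!rec$doc_id %in% names(index$documents)) {
      stop("chunk '", rec$chunk_id, "' references unknown doc_id '",
           rec$doc_id, "'")
    }
    chunks[[rec$chunk_id]] <- chunk_record(rec$chunk_id, rec$doc_id, rec$level,
                                           rec$text, rec$char_start, rec$char_end)
    by_level[[rec$level]] <- c(by_level[[rec$level]], rec$chunk_id)
  }
  index$chunks <- chunks
  index$by_level <- by_level
  index
}
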