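## Readers and writers for the BioNLP standoff annotation format (.txt /
## .a1 / .a2) and for the tabular dependency-parse files that accompany
## each document.  Offsets are 0-based half-open throughout.

#' Parse a .a1 protein annotation file
#'
#' Each line has the form \code{"T1\tProtein <start> <end>\t<surface>"}.
#'
#' @param lines character vector of lines (or a single string with
#'   embedded newlines).
#' @param text optional document text; when given, each mention's surface
#'   string is verified against \code{substr(text, start+1, end)}.
#' @return data.frame with columns ann_id, char_start, char_end, surface.
#' @export
parse_a1 <- function(lines, text = NULL) {
  lines <- split_lines(lines)
  out <- data.frame(ann_id = character(), char_start = integer(),
                    char_end = integer(), surface = character())
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln)) next
    m <- regmatches(ln, regexec("^(T[0-9]+)\t(\\S+) ([0-9]+) ([0-9]+)\t(.*)$", ln))[[1]]
    if (length(m) != 6L || m[3] != "Protein")
      stop("malformed .a1 line ", i, ": ", ln)
    st <- as.integer(m[4]); en <- as.integer(m[5])
    if (en <= st) stop("invalid span on .a1 line ", i, " (end <= start)")
    if (!is.null(text) && substr(text, st + 1L, en) != m[6])
      stop("span/surface mismatch on .a1 line ", i, ": expected '", m[6],
           "' got '", substr(text, st + 1L, en), "'")
    out <- rbind(out, data.frame(ann_id = m[2], char_start = st,
                                 char_end = en, surface = m[6]))
  }
  if (anyDuplicated(out$ann_id)) stop("duplicate annotation id in .a1")
  out
}

#' Parse a .a2 event annotation file
#'
#' Trigger lines look like \code{"T5\tGene_expression 10 20\tproduction"};
#' event lines like \code{"E1\tGene_expression:T5 Theme:T1"} with argument
#' keys Theme, Theme2, ... (multi-Theme Binding) and an optional Cause.
#' Arguments reference protein T-ids from the .a1 file or other E-ids
#' (nested events).  The event reference graph must be acyclic.
#'
#' @param lines character vector of .a2 lines.
#' @param proteins data.frame from [parse_a1()].
#' @return list with elements \code{triggers} (data.frame ann_id, type,
#'   char_start, char_end, surface) and \code{events} (list of records with
#'   ann_id, type, trigger_id, themes, cause).
#' @export
parse_a2 <- function(lines, proteins) {
  lines <- split_lines(lines)
  triggers <- data.frame(ann_id = character(), type = character(),
                         char_start = integer(), char_end = integer(),
                         surface = character())
  events <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln)) next
    if (startsWith(ln, "T")) {
      m <- regmatches(ln, regexec("^(T[0-9]+)\t(\\S+) ([0-9]+) ([0-9]+)\t(.*)$", ln))[[1]]
      if (length(m) != 6L) stop("malformed .a2 trigger line ", i, ": ", ln)
      if (!(m[3] %in% EVENT_TYPES)) stop("unknown event type on line ", i, ": ", m[3])
      st <- as.integer(m[4]); en <- as.integer(m[5])
      if (en <= st) stop("invalid span on .a2 line ", i)
      triggers <- rbind(triggers, data.frame(
        ann_id = m[2], type = m[3], char_start = st, char_end = en,
        surface = m[6]))
    } else if (startsWith(ln, "E")) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) != 2L) stop("malformed .a2 event line ", i, ": ", ln)
      eid <- parts[1]
      args <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
      head_kv <- strsplit(args[1], ":", fixed = TRUE)[[1]]
      type <- head_kv[1]; trig_id <- head_kv[2]
      if (!(type %in% EVENT_TYPES)) stop("unknown event type on line ", i)
      themes <- list(); cause <- NULL
      for (a in args[-1]) {
        kv <- strsplit(a, ":", fixed = TRUE)[[1]]
        ref <- list(kind = if (startsWith(kv[2], "E")) "event" else "protein",
                    id = kv[2])
        if (grepl("^Theme[0-9]*$", kv[1])) themes <- c(themes, list(ref))
        else if (kv[1] == "Cause") cause <- ref
        else stop("unknown argument key '", kv[1], "' on line ", i)
      }
      if (!length(themes)) stop("event without Theme on line ", i)
      events[[length(events) + 1L]] <- list(
        ann_id = eid, type = type, trigger_id = trig_id,
        themes = themes, cause = cause)
    } else stop("unrecognized .a2 line ", i, ": ", ln)
  }
  validate_events(events, triggers, proteins)
  list(triggers = triggers, events = events)
}

validate_events <- function(events, triggers, proteins) {
  eids <- vapply(events, function(e) e$ann_id, "")
  if (anyDuplicated(eids)) stop("duplicate event id in .a2")
  refs_of <- function(e) {
    ids <- vapply(e$themes, function(a) if (a$kind == "event") a$id else NA_character_, "")
    if (!is.null(e$cause) && e$cause$kind == "event") ids <- c(ids, e$cause$id)
    ids[!is.na(ids)]
  }
  for (e in events) {
    if (!(e$trigger_id %in% triggers$ann_id))
      stop("dangling trigger reference ", e$trigger_id, " in ", e$ann_id)
    for (a in e$themes) {
      if (a$kind == "protein" && !(a$id %in% proteins$ann_id))
        stop("dangling protein reference ", a$id, " in ", e$ann_id)
      if (a$kind == "event" && !(a$id %in% eids))
        stop("dangling event reference ", a$id, " in ", e$ann_id)
    }
    if (!is.null(e$cause)) {
      a <- e$cause
      if (a$kind == "protein" && !(a$id %in% proteins$ann_id))
        stop("dangling protein reference ", a$id, " in ", e$ann_id)
      if (a$kind == "event" && !(a$id %in% eids))
        stop("dangling event reference ", a$id, " in ", e$ann_id)
    }
  }
  ## cycle check over event->event references (DFS with colouring)
  adj <- lapply(events, refs_of)
  names(adj) <- eids
  state <- new.env(parent = emptyenv())
  visit <- function(id) {
    s <- state[[id]] %||% 0L
    if (s == 1L) stop("cyclic event references involving ", id)
    if (s == 2L) return(invisible())
    state[[id]] <- 1L
    for (r in adj[[id]]) visit(r)
    state[[id]] <- 2L
  }
  for (id in eids) visit(id)
  invisible(TRUE)
}

#' Serialize triggers and events to .a2 text
#'
#' Inverse of [parse_a2()]: emits one T-line per trigger and one E-line per
#' event, with multi-Theme arguments keyed Theme, Theme2, Theme3, ...
#'
#' @param triggers data.frame with columns ann_id, type, char_start,
#'   char_end, surface.
#' @param events list of event records as in [parse_a2()].
#' @return a single string of .a2 content.
#' @export
write_a2 <- function(triggers, events) {
  if (nrow(triggers) && any(is.na(triggers$ann_id) | !nzchar(triggers$ann_id)))
    stop("trigger without assigned id")
  tl <- sprintf("%s\t%s %d %d\t%s", triggers$ann_id, triggers$type,
                triggers$char_start, triggers$char_end, triggers$surface)
  el <- vapply(events, function(e) {
    if (is.null(e$ann_id) || !nzchar(e$ann_id)) stop("event without assigned id")
    keys <- c("Theme", paste0("Theme", seq_along(e$themes))[-1])
    args <- paste0(keys, ":", vapply(e$themes, function(a) a$id, ""))
    if (!is.null(e$cause)) args <- c(args, paste0("Cause:", e$cause$id))
    sprintf("%s\t%s:%s %s", e$ann_id, e$type, e$trigger_id,
            paste(args, collapse = " "))
  }, "")
  paste(c(tl, el), collapse = "\n")
}

#' Parse a dependency-parse file and attach sentences to a document
#'
#' One blank-line-separated block per sentence; each token line has
#' tab-separated fields \code{index, surface, lemma, pos, char_start,
#' char_end, deps} where \code{deps} is a space-separated list of
#' \code{head:label} pairs ("_" when the token has no incoming edges, i.e.
#' it is never a dependent).
#'
#' @param lines character vector of parse-file lines.
#' @param text document text the offsets refer to.
#' @return list of [new_sentence()] objects (without annotations attached).
#' @export
parse_parses <- function(lines, text) {
  lines <- split_lines(lines)
  blocks <- split(lines, cumsum(!nzchar(lines)))
  blocks <- lapply(blocks, function(b) b[nzchar(b)])
  blocks <- blocks[vapply(blocks, length, 0L) > 0L]
  sentences <- vector("list", length(blocks))
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    toks <- list(); deps <- list()
    for (ln in b) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) != 7L) stop("malformed parse line: ", ln)
      idx <- as.integer(f[1])
      st <- as.integer(f[5]); en <- as.integer(f[6])
      if (substr(text, st + 1L, en) != f[2])
        stop("token/offset mismatch for '", f[2], "' at ", st, "..", en)
      toks[[length(toks) + 1L]] <- data.frame(
        index = idx, surface = f[2], lemma = f[3], pos = f[4],
        char_start = st, char_end = en)
      if (f[7] != "_") {
        for (hp in strsplit(f[7], " ", fixed = TRUE)[[1]]) {
          kv <- regmatches(hp, regexec("^([0-9]+):(.+)$", hp))[[1]]
          if (length(kv) != 3L) stop("malformed dependency '", hp, "'")
          deps[[length(deps) + 1L]] <- data.frame(
            head = as.integer(kv[2]), dependent = idx, label = kv[3])
        }
      }
    }
    tokens <- do.call(rbind, toks)
    if (anyDuplicated(tokens$index)) stop("duplicate token index in sentence ", bi)
    tokens <- tokens[order(tokens$index), , drop = FALSE]
    rownames(tokens) <- NULL
    dd <- if (length(deps)) do.call(rbind, deps) else NULL
    sentences[[bi]] <- new_sentence(tokens, dd, index = bi - 1L)
  }
  sentences
}

## token (0-based index) whose span overlaps [st, en) with maximal overlap;
## ties broken towards the leftmost token.
locate_head_token <- function(tokens, st, en) {
  ov <- pmin(tokens$char_end, en) - pmax(tokens$char_start, st)
  ov[ov < 0L] <- 0L
  if (all(ov == 0L)) return(NA_integer_)
  tokens$index[which.max(ov)]
}

#' Read one standoff document from a directory
#'
#' Expects \code{<doc_id>.txt}, \code{<doc_id>.a1},
#' \code{<doc_id>.parses} and optionally \code{<doc_id>.a2}.  Protein
#' mentions and gold triggers are assigned to the sentence whose span
#' contains them; multi-token gold triggers are reduced to their syntactic
#' head token.
#'
#' @param dir corpus directory.
#' @param doc_id document id (file stem).
#' @param domain "abstract" or "fullpaper".
#' @param read_gold read the .a2 file when present.
#' @return a [new_document()] object.
#' @export
read_document <- function(dir, doc_id, domain = "abstract", read_gold = TRUE) {
  text <- read_file(file.path(dir, paste0(doc_id, ".txt")))
  prot <- parse_a1(read_file(file.path(dir, paste0(doc_id, ".a1"))), text)
  sentences <- parse_parses(read_file(file.path(dir, paste0(doc_id, ".parses"))), text)
  a2_path <- file.path(dir, paste0(doc_id, ".a2"))
  gold <- if (read_gold && file.exists(a2_path))
    parse_a2(read_file(a2_path), prot) else NULL

  sent_range <- vapply(sentences, function(s)
    c(min(s$tokens$char_start), max(s$tokens$char_end)), c(0, 0))
  in_sentence <- function(st, en) {
    hit <- which(st >= sent_range[1, ] & en <= sent_range[2, ])
    if (length(hit) != 1L)
      stop("annotation span ", st, "..", en,
           " does not fall inside exactly one sentence")
    hit
  }

  for (i in seq_len(nrow(prot))) {
    si <- in_sentence(prot$char_start[i], prot$char_end[i])
    s <- sentences[[si]]
    ht <- locate_head_token(s$tokens, prot$char_start[i], prot$char_end[i])
    if (is.na(ht)) stop("protein ", prot$ann_id[i], " overlaps no token")
    s$proteins <- rbind(s$proteins, data.frame(
      ann_id = prot$ann_id[i], char_start = prot$char_start[i],
      char_end = prot$char_end[i], head_token = ht))
    sentences[[si]] <- s
  }

  if (!is.null(gold)) {
    tr <- gold$triggers
    tr_sent <- integer(nrow(tr))
    tr$head_token <- NA_integer_
    for (i in seq_len(nrow(tr))) {
      si <- in_sentence(tr$char_start[i], tr$char_end[i])
      tr_sent[i] <- si
      tr$head_token[i] <- trigger_head_token(sentences[[si]],
                                             tr$char_start[i], tr$char_end[i])
    }
    ev_sent <- vapply(gold$events, function(e)
      tr_sent[match(e$trigger_id, tr$ann_id)], 0L)
    for (si in seq_along(sentences)) {
      s <- sentences[[si]]
      sel <- tr_sent == si
      s$gold_triggers <- tr[sel, c("ann_id", "type", "char_start",
                                   "char_end", "head_token")]
      rownames(s$gold_triggers) <- NULL
      s$gold_events <- gold$events[ev_sent == si]
      sentences[[si]] <- s
    }
  }
  new_document(doc_id, text, sentences, domain)
}

#' Read a standoff corpus directory
#'
#' The directory holds per-document .txt/.a1/.parses (and optionally .a2)
#' files plus a \code{domains.tsv} manifest mapping doc_id to domain
#' ("abstract" or "fullpaper"); documents absent from the manifest default
#' to "abstract".
#'
#' @param dir corpus directory.
#' @param read_gold read .a2 files when present.
#' @return list of [new_document()] objects, named by doc_id.
#' @export
read_corpus <- function(dir, read_gold = TRUE) {
  ids <- sort(sub("\\.txt$", "", basename(Sys.glob(file.path(dir, "*.txt")))))
  man_path <- file.path(dir, "domains.tsv")
  domains <- stats::setNames(rep("abstract", length(ids)), ids)
  if (file.exists(man_path)) {
    man <- utils::read.table(man_path, sep = "\t", header = FALSE,
                             col.names = c("doc_id", "domain"),
                             stringsAsFactors = FALSE)
    domains[man$doc_id] <- man$domain
  }
  docs <- lapply(ids, function(id)
    read_document(dir, id, domain = domains[[id]], read_gold = read_gold))
  stats::setNames(docs, ids)
}

#' Write a corpus of documents to a standoff directory
#'
#' Emits .txt, .a1, .parses, the domains.tsv manifest and, for documents
#' carrying gold annotation, .a2 files.  [read_corpus()] on the result
#' reproduces the annotations (up to annotation-id renaming).
#'
#' @param docs list of [new_document()] objects.
#' @param dir output directory (created if missing).
#' @export
write_corpus <- function(docs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- character()
  for (doc in docs) {
    id <- doc$doc_id
    write_file(doc$text, file.path(dir, paste0(id, ".txt")))
    a1 <- character(); parses <- character()
    triggers <- NULL; events <- list()
    for (s in doc$sentences) {
      if (nrow(s$proteins)) {
        surf <- substring(doc$text, s$proteins$char_start + 1L, s$proteins$char_end)
        a1 <- c(a1, sprintf("%s\tProtein %d %d\t%s", s$proteins$ann_id,
                            s$proteins$char_start, s$proteins$char_end, surf))
      }
      dep_str <- vapply(s$tokens$index, function(i) {
        dd <- s$deps[s$deps$dependent == i, , drop = FALSE]
        if (!nrow(dd)) "_" else paste(sprintf("%d:%s", dd$head, dd$label),
                                      collapse = " ")
      }, "")
      parses <- c(parses, sprintf("%d\t%s\t%s\t%s\t%d\t%d\t%s",
                                  s$tokens$index, s$tokens$surface,
                                  s$tokens$lemma, s$tokens$pos,
                                  s$tokens$char_start, s$tokens$char_end,
                                  dep_str), "")
      if (!is.null(s$gold_triggers) && nrow(s$gold_triggers)) {
        tr <- s$gold_triggers
        tr$surface <- substring(doc$text, tr$char_start + 1L, tr$char_end)
        triggers <- rbind(triggers, tr[, c("ann_id", "type", "char_start",
                                           "char_end", "surface")])
      }
      events <- c(events, s$gold_events %||% list())
    }
    write_file(paste(a1, collapse = "\n"), file.path(dir, paste0(id, ".a1")), eol = TRUE)
    write_file(paste(parses, collapse = "\n"), file.path(dir, paste0(id, ".parses")), eol = TRUE)
    if (!is.null(triggers))
      write_file(write_a2(triggers, events), file.path(dir, paste0(id, ".a2")), eol = TRUE)
    man <- c(man, paste(id, doc$domain, sep = "\t"))
  }
  write_file(paste(man, collapse = "\n"), file.path(dir, "domains.tsv"), eol = TRUE)
  invisible(dir)
}

split_lines <- function(x) {
  if (length(x) == 1L && grepl("\n", x, fixed = TRUE))
    x <- strsplit(x, "\n", fixed = TRUE)[[1]]
  x
}

read_file <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  readChar(path, file.info(path)$size, useBytes = TRUE)
}

## .txt content is written byte-faithfully; annotation and parse files get
## a final newline.
write_file <- function(x, path, eol = FALSE) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(if (eol) paste0(x, "\n") else x, con, eos = NULL, useBytes = TRUE)
}
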