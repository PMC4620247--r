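# RDF triple content model.  A patient summary is a set of triples over a
# small common-information-model vocabulary (classes Patient, Condition,
# Observation; predicates for code, codeSystem, startDate, value, unit,
# date).  Serialization is Turtle, one triple per statement line.
# Extraction scripts against this model are SPARQL SELECT queries
# restricted to a basic graph pattern plus FILTER equality — enough for
# every schema item in the shipped study configuration, and small enough
# that a brute-force join oracle stays feasible in tests.
#
# Term encoding used throughout: IRIs as "<full-iri>", literals as
# "\"lexical-form\"".  Variables in patterns as "?name".

CIM_NS <- "http://cdelink.example.org/cim#"
RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
DEFAULT_PREFIXES <- c(cim = CIM_NS, rdf = RDF_NS)
RDF_TYPE <- paste0("<", RDF_NS, "type>")

iri <- function(x) paste0("<", x, ">")
lit <- function(x) paste0("\"", x, "\"")
is_lit <- function(x) startsWith(x, "\"")
is_var <- function(x) startsWith(x, "?")
lit_value <- function(x) substr(x, 2L, nchar(x) - 1L)
local_name <- function(x) sub("^<.*[#/]", "", sub(">$", "", x))

#' Construct a graph patient summary
#'
#' @param triples Data frame with character columns `s`, `p`, `o` in the
#'   package's term encoding (IRIs in angle brackets, literals quoted).
#' @param patient_subject IRI of the single patient node.
#' @param patient_id Patient identifier string.
#' @return An object of class `graph_summary`.
#' @export
graph_summary <- function(triples, patient_subject, patient_id = local_name(patient_subject)) {
  stopifnot(is.data.frame(triples), all(c("s", "p", "o") %in% names(triples)))
  structure(list(triples = triples, patient_subject = patient_subject,
                 patient_id = patient_id),
            class = "graph_summary")
}

#' @export
print.graph_summary <- function(x, ...) {
  cat(sprintf("<graph_summary> patient %s, %d triples\n", x$patient_id, nrow(x$triples)))
  invisible(x)
}

#' Serialize a graph summary to Turtle
#'
#' One triple per line; `rdf:type` written as `a`. Parsing the result
#' with [parse_turtle()] reproduces the triple set exactly.
#'
#' @param gs A `graph_summary`.
#' @return A single Turtle string.
#' @export
write_turtle <- function(gs) {
  tr <- gs$triples
  qn <- function(x) {
    out <- x
    for (pre in names(DEFAULT_PREFIXES)) {
      ns <- DEFAULT_PREFIXES[[pre]]
      hit <- !is_lit(out) & startsWith(out, paste0("<", ns))
      out[hit] <- paste0(pre, ":", sub(">$", "", sub(paste0("^<", ns), "", out[hit])))
    }
    out
  }
  p <- qn(tr$p)
  p[tr$p == RDF_TYPE] <- "a"
  paste0(c(
    sprintf("@prefix %s: <%s> .", names(DEFAULT_PREFIXES), unname(DEFAULT_PREFIXES)),
    "",
    sprintf("%s %s %s .", qn(tr$s), p, qn(tr$o))
  ), collapse = "\n")
}

tokenize_ttl_line <- function(line) {
  toks <- character(0)
  i <- 1L; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch == "\"") {
      j <- i + 1L
      while (j <= n && substr(line, j, j) != "\"") j <- j + 1L
      toks <- c(toks, substr(line, i, j)); i <- j + 1L
    } else if (ch == "<") {
      j <- regexpr(">", substr(line, i, n), fixed = TRUE)
      toks <- c(toks, substr(line, i, i + j - 1L)); i <- i + j
    } else {
      j <- i
      while (j <= n && !(substr(line, j, j) %in% c(" ", "\t"))) j <- j + 1L
      toks <- c(toks, substr(line, i, j - 1L)); i <- j
    }
  }
  toks
}

expand_term <- function(tok, prefixes) {
  if (startsWith(tok, "<") || startsWith(tok, "\"") || startsWith(tok, "?")) return(tok)
  if (tok == "a") return(RDF_TYPE)
  m <- regmatches(tok, regexec("^([A-Za-z][A-Za-z0-9_]*):(.*)$", tok))[[1]]
  if (length(m) == 3 && m[2] %in% names(prefixes)) {
    return(iri(paste0(prefixes[[m[2]]], m[3])))
  }
  abort_cdelink(sprintf("cannot resolve term '%s'", tok), "cdelink_spec_error")
}

#' Parse a Turtle document into a graph summary
#'
#' Supports the subset [write_turtle()] emits: `@prefix` declarations
#' and one `subject predicate object .` statement per line.
#'
#' @param text Turtle text (single string or character vector of lines).
#' @return A `graph_summary`; the patient subject is the unique node
#'   typed `cim:Patient`.
#' @export
parse_turtle <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  prefixes <- character(0)
  s <- p <- o <- character(0)
  for (line in lines) {
    if (startsWith(line, "@prefix")) {
      m <- regmatches(line, regexec("^@prefix\\s+([A-Za-z][A-Za-z0-9_]*):\\s*<([^>]*)>", line))[[1]]
      prefixes[m[2]] <- m[3]
      next
    }
    toks <- tokenize_ttl_line(line)
    if (length(toks) && toks[length(toks)] == ".") toks <- toks[-length(toks)]
    if (length(toks) != 3) {
      abort_cdelink(sprintf("malformed Turtle statement: '%s'", line), "cdelink_spec_error")
    }
    s <- c(s, expand_term(toks[1], prefixes))
    p <- c(p, expand_term(toks[2], prefixes))
    o <- c(o, expand_term(toks[3], prefixes))
  }
  tr <- data.frame(s = s, p = p, o = o, stringsAsFactors = FALSE)
  pat <- tr$s[tr$p == RDF_TYPE & tr$o == iri(paste0(CIM_NS, "Patient"))]
  if (length(pat) != 1) {
    abort_cdelink(sprintf("graph summary must contain exactly one cim:Patient node (found %d)",
                          length(pat)), "cdelink_data_quality_error")
  }
  ids <- tr$o[tr$s == pat & tr$p == iri(paste0(CIM_NS, "patientId"))]
  graph_summary(tr, pat, if (length(ids)) lit_value(ids[1]) else local_name(pat))
}

# ---- SPARQL SELECT subset -------------------------------------------------

#' Parse a graph-pattern extraction script
#'
#' Accepts `PREFIX` declarations followed by
#' `SELECT ?entry ?value [?system] WHERE { pattern . pattern . FILTER(?v = "x") }`.
#' Patterns are triple patterns over variables, prefixed names, IRIs and
#' literals; `a` abbreviates `rdf:type`. `FILTER` supports equality of a
#' variable against a literal only.
#'
#' @param script Query text.
#' @return A list with `vars`, `patterns` (list of 3-term character
#'   vectors) and `filters` (named character vector var -> literal).
#' @export
parse_graph_pattern <- function(script) {
  prefixes <- DEFAULT_PREFIXES
  for (m in regmatches(script, gregexpr("PREFIX\\s+([A-Za-z][A-Za-z0-9_]*):\\s*<([^>]*)>",
                                        script, ignore.case = TRUE))[[1]]) {
    mm <- regmatches(m, regexec("([A-Za-z][A-Za-z0-9_]*):\\s*<([^>]*)>", m))[[1]]
    prefixes[mm[2]] <- mm[3]
  }
  m <- regmatches(script, regexec("SELECT\\s+([^{]*?)\\s*WHERE\\s*\\{(.*)\\}",
                                  script, ignore.case = TRUE))[[1]]
  if (length(m) != 3) {
    abort_cdelink("malformed graph-pattern script: expected SELECT ... WHERE { ... }",
                  "cdelink_spec_error")
  }
  vars <- regmatches(m[2], gregexpr("\\?[A-Za-z][A-Za-z0-9_]*", m[2]))[[1]]
  if (!length(vars)) abort_cdelink("graph-pattern script projects no variables",
                                   "cdelink_spec_error")
  body <- m[3]
  filters <- character(0)
  fm <- regmatches(body, gregexpr("FILTER\\s*\\(\\s*(\\?[A-Za-z][A-Za-z0-9_]*)\\s*=\\s*(\"[^\"]*\")\\s*\\)",
                                  body, ignore.case = TRUE))[[1]]
  for (f in fm) {
    mm <- regmatches(f, regexec("(\\?[A-Za-z][A-Za-z0-9_]*)\\s*=\\s*(\"[^\"]*\")", f))[[1]]
    filters[mm[2]] <- mm[3]
  }
  body <- gsub("FILTER\\s*\\([^)]*\\)", "", body, ignore.case = TRUE)
  stmts <- trimws(strsplit(body, ".", fixed = TRUE)[[1]])
  stmts <- stmts[nzchar(stmts)]
  patterns <- lapply(stmts, function(st) {
    toks <- tokenize_ttl_line(st)
    if (length(toks) != 3) {
      abort_cdelink(sprintf("malformed triple pattern: '%s'", st), "cdelink_spec_error")
    }
    vapply(toks, expand_term, "", prefixes = prefixes)
  })
  if (!length(patterns)) abort_cdelink("empty basic graph pattern", "cdelink_spec_error")
  list(vars = vars, patterns = patterns, filters = filters)
}

#' Match a basic graph pattern against a triple set
#'
#' Successive join evaluation: each triple pattern is matched against
#' all triples and joined with the bindings accumulated so far on the
#' shared variables; FILTER equalities are applied at the end.
#'
#' @param triples Triple data frame (`s`, `p`, `o`).
#' @param query Parsed query from [parse_graph_pattern()].
#' @return Data frame of solution bindings, one column per projected
#'   variable (named without the leading `?`).
#' @export
cross_join_df <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    out <- cbind(a[0, , drop = FALSE], b[0, , drop = FALSE])
    rownames(out) <- NULL
    return(out)
  }
  ia <- rep(seq_len(nrow(a)), each = nrow(b))
  ib <- rep.int(seq_len(nrow(b)), nrow(a))
  out <- cbind(a[ia, , drop = FALSE], b[ib, , drop = FALSE])
  rownames(out) <- NULL
  out
}

match_bgp <- function(triples, query) {
  bind <- data.frame(.dummy = 1)
  for (pat in query$patterns) {
    cand <- triples
    varcols <- character(0)  # names: s/p/o column, values: variable name
    for (k in 1:3) {
      term <- pat[k]
      col <- c("s", "p", "o")[k]
      if (is_var(term)) {
        varcols[col] <- substring(term, 2)
      } else {
        cand <- cand[cand[[col]] == term, , drop = FALSE]
      }
    }
    # a variable repeated within one pattern must bind consistently
    if (anyDuplicated(varcols)) {
      for (v in unique(varcols[duplicated(varcols)])) {
        cc <- names(varcols)[varcols == v]
        keep <- rep(TRUE, nrow(cand))
        for (extra in cc[-1]) keep <- keep & (cand[[extra]] == cand[[cc[1]]])
        cand <- cand[keep, , drop = FALSE]
      }
      varcols <- varcols[!duplicated(varcols)]
    }
    if (!length(varcols)) {  # fully ground pattern: acts as an assertion
      if (!nrow(cand)) { bind <- bind[0, , drop = FALSE]; break }
      next
    }
    cand <- cand[, names(varcols), drop = FALSE]
    names(cand) <- unname(varcols)
    shared <- intersect(names(bind), names(cand))
    bind <- if (length(shared)) {
      merge(bind, cand, by = shared, sort = FALSE)
    } else {
      cross_join_df(bind, cand)
    }
    if (!nrow(bind)) break
  }
  bind$.dummy <- NULL
  for (v in names(query$filters)) {
    nm <- substring(v, 2)
    if (nm %in% names(bind)) bind <- bind[bind[[nm]] == query$filters[[v]], , drop = FALSE]
  }
  # solutions are distinct assignments of the pattern variables; the
  # projection keeps multiset semantics
  proj <- substring(query$vars, 2)
  for (mv in setdiff(proj, names(bind))) bind[[mv]] <- rep(NA_character_, nrow(bind))
  bind <- unique(bind)
  out <- bind[, proj, drop = FALSE]
  rownames(out) <- NULL
  out
}
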