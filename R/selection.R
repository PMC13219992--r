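# Atom-selection mini-language.
#
# Grammar (case-insensitive keywords, whitespace-tokenized):
#   expr    := orexpr
#   orexpr  := andexpr ('or' andexpr)*
#   andexpr := unary ('and' unary)*
#   unary   := 'not' unary | '(' expr ')' | primary
#   primary := 'all' | 'protein' | 'ligand' | 'heavy' | 'hydrogen'
#            | 'name' LIST | 'element' LIST | 'resname' LIST
#            | 'chain' LIST | 'resid' RANGELIST
# LIST is a single token or comma-separated tokens (no spaces); RANGELIST
# additionally allows inclusive ranges "60-69". Values are matched
# case-sensitively except chain, element and keywords.

#' Select atoms by expression
#'
#' Resolves a selection expression against a topology. Resolution is
#' deterministic: the result is a sorted set of 0-based atom indices.
#' `"heavy"` excludes hydrogens; `"protein"`/`"ligand"` follow the
#' topology's partition.
#'
#' @param top A [topology()].
#' @param expression Selection string, e.g. `"ligand and heavy"`,
#'   `"protein and name CA"`, `"chain A and resid 60-69"`.
#' @return Object of class `"atom_selection"`: list with `expression` and
#'   `resolved` (sorted 0-based integer indices). Empty results warn but do
#'   not error.
#' @export
select_atoms <- function(top, expression) {
  stopifnot(inherits(top, "topology"))
  toks <- sel_tokenize(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  mask <- sel_parse_or(st, top)
  if (st$pos <= length(st$toks))
    stop_selection(sprintf("selection syntax error near '%s' in \"%s\"",
                           st$toks[st$pos], expression))
  idx <- top$atoms$index[mask]
  if (length(idx) == 0L)
    warning(sprintf("selection \"%s\" matched no atoms", expression),
            call. = FALSE)
  structure(list(expression = expression, resolved = sort(as.integer(idx))),
            class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat(sprintf("<atom_selection> \"%s\": %d atoms\n", x$expression,
              length(x$resolved)))
  invisible(x)
}

sel_tokenize <- function(expression) {
  if (!is.character(expression) || length(expression) != 1L || is.na(expression))
    stop_selection("selection expression must be a single string")
  s <- gsub("\\(", " ( ", expression)
  s <- gsub("\\)", " ) ", s)
  toks <- strsplit(trimws(s), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L) stop_selection("empty selection expression")
  toks
}

sel_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_
sel_next <- function(st) { t <- sel_peek(st); st$pos <- st$pos + 1L; t }

sel_parse_or <- function(st, top) {
  m <- sel_parse_and(st, top)
  while (!is.na(sel_peek(st)) && tolower(sel_peek(st)) == "or") {
    sel_next(st)
    m <- m | sel_parse_and(st, top)
  }
  m
}

sel_parse_and <- function(st, top) {
  m <- sel_parse_unary(st, top)
  while (!is.na(sel_peek(st)) && tolower(sel_peek(st)) == "and") {
    sel_next(st)
    m <- m & sel_parse_unary(st, top)
  }
  m
}

sel_parse_unary <- function(st, top) {
  t <- sel_peek(st)
  if (is.na(t)) stop_selection("unexpected end of selection expression")
  if (tolower(t) == "not") {
    sel_next(st)
    return(!sel_parse_unary(st, top))
  }
  if (t == "(") {
    sel_next(st)
    m <- sel_parse_or(st, top)
    if (is.na(sel_peek(st)) || sel_peek(st) != ")")
      stop_selection("unbalanced parenthesis in selection expression")
    sel_next(st)
    return(m)
  }
  sel_parse_primary(st, top)
}

sel_parse_primary <- function(st, top) {
  a <- top$atoms
  t <- tolower(sel_next(st))
  switch(t,
    all = rep(TRUE, nrow(a)),
    protein = !a$is_ligand,
    ligand = a$is_ligand,
    heavy = !a$is_hydrogen,
    hydrogen = a$is_hydrogen,
    name = a$name %in% sel_values(st, "name"),
    resname = a$resname %in% sel_values(st, "resname"),
    element = toupper(a$element) %in% toupper(sel_values(st, "element")),
    chain = toupper(a$chain) %in% toupper(sel_values(st, "chain")),
    resid = a$resseq %in% sel_resid_values(st),
    stop_selection(sprintf("unknown selection keyword '%s'", t))
  )
}

sel_values <- function(st, what) {
  v <- sel_next(st)
  if (is.na(v) || tolower(v) %in% c("and", "or", "not", "(", ")"))
    stop_selection(sprintf("'%s' requires a value", what))
  strsplit(v, ",")[[1]]
}

sel_resid_values <- function(st) {
  parts <- sel_values(st, "resid")
  out <- integer(0)
  for (p in parts) {
    if (grepl("^-?[0-9]+--?[0-9]+$", p) || grepl("^[0-9]+-[0-9]+$", p)) {
      ab <- regmatches(p, regexec("^(-?[0-9]+)-(-?[0-9]+)$", p))[[1]][2:3]
      ab <- as.integer(ab)
      out <- c(out, seq(ab[1], ab[2]))
    } else if (grepl("^-?[0-9]+$", p)) {
      out <- c(out, as.integer(p))
    } else {
      stop_selection(sprintf("bad resid token '%s'", p))
    }
  }
  out
}

# Resolve either an atom_selection or an expression string; internal helper.
resolve_selection <- function(top, sel) {
  if (inherits(sel, "atom_selection")) return(sel$resolved)
  if (is.character(sel)) return(select_atoms(top, sel)$resolved)
  if (is.numeric(sel)) return(sort(as.integer(sel)))
  stop_selection("selection must be an atom_selection, expression string or index vector")
}
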