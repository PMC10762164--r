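#' Atom selections
#'
#' Selections are expressed in a small grammar and resolved against a
#' `structure_model` to a sorted set of unique atom indices. The grammar
#' (EBNF):
#'
#' ```
#' expr      = term , { "or" , term } ;
#' term      = factor , { "and" , factor } ;
#' factor    = "not" , factor | "(" , expr , ")" | primitive ;
#' primitive = "chain"   , id  , { id }
#'           | "resid"   , ridspec , { ridspec }
#'           | "resname" , id  , { id }
#'           | "name"    , id  , { id }
#'           | "element" , id  , { id }
#'           | "protein" | "backbone" | "calpha" | "all" | "none" ;
#' ridspec   = integer | integer , ":" , integer ;
#' ```
#'
#' Examples: `"resid 201:322 and name CA"`, `"chain A B"`,
#' `"protein and not backbone"`, `"name P"`.
#' An expression that resolves to zero atoms is a valid empty selection;
#' a malformed expression is a parse error.
#'
#' @param model a `structure_model`
#' @param expression selection string in the grammar above
#' @return an `atom_selection`: list with `expression` and sorted unique
#'   `indices` into the model
#' @examples
#' m <- make_toy_pentamer(seed = 1)
#' ca <- select_atoms(m, "calpha and resid 201:322")
#' length(selection_indices(ca))
#' @export
select_atoms <- function(model, expression) {
  stopifnot(inherits(model, "structure_model"), is.character(expression),
            length(expression) == 1L)
  toks <- sel_tokenize(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L
  mask <- sel_parse_expr(st, model)
  if (st$pos <= length(st$toks))
    stop("selection parse error: unexpected token '",
         st$toks[st$pos], "' in: ", expression)
  structure(list(expression = expression,
                 indices = which(mask)),
            class = "atom_selection")
}

#' Build a selection from explicit indices
#' @param indices integer atom indices (deduplicated, sorted)
#' @param expression optional label
#' @export
atom_selection <- function(indices, expression = "<indices>") {
  structure(list(expression = expression,
                 indices = sort(unique(as.integer(indices)))),
            class = "atom_selection")
}

#' Indices of an atom selection
#' @param selection an `atom_selection` or plain integer vector
#' @export
selection_indices <- function(selection) {
  if (inherits(selection, "atom_selection")) selection$indices
  else as.integer(selection)
}

#' @export
print.atom_selection <- function(x, ...) {
  cat(sprintf("<atom_selection> '%s': %d atoms\n", x$expression,
              length(x$indices)))
  invisible(x)
}

#' Combine selections
#' @param a,b `atom_selection` objects on the same model
#' @name selection-algebra
#' @export
selection_union <- function(a, b) {
  atom_selection(union(selection_indices(a), selection_indices(b)),
                 paste0("(", a$expression, ") or (", b$expression, ")"))
}

#' @rdname selection-algebra
#' @export
selection_intersect <- function(a, b) {
  atom_selection(intersect(selection_indices(a), selection_indices(b)),
                 paste0("(", a$expression, ") and (", b$expression, ")"))
}

## --- grammar internals -----------------------------------------------------

AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL")

sel_tokenize <- function(expression) {
  s <- gsub("([()])", " \\1 ", expression)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  if (!length(toks)) stop("selection parse error: empty expression")
  toks
}

sel_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA
sel_next <- function(st) { t <- sel_peek(st); st$pos <- st$pos + 1L; t }

sel_parse_expr <- function(st, model) {
  mask <- sel_parse_term(st, model)
  while (!is.na(sel_peek(st)) && tolower(sel_peek(st)) == "or") {
    sel_next(st)
    mask <- mask | sel_parse_term(st, model)
  }
  mask
}

sel_parse_term <- function(st, model) {
  mask <- sel_parse_factor(st, model)
  while (!is.na(sel_peek(st)) && tolower(sel_peek(st)) == "and") {
    sel_next(st)
    mask <- mask & sel_parse_factor(st, model)
  }
  mask
}

sel_parse_factor <- function(st, model) {
  tok <- sel_peek(st)
  if (is.na(tok)) stop("selection parse error: unexpected end of expression")
  lt <- tolower(tok)
  if (lt == "not") {
    sel_next(st)
    return(!sel_parse_factor(st, model))
  }
  if (tok == "(") {
    sel_next(st)
    mask <- sel_parse_expr(st, model)
    if (is.na(sel_peek(st)) || sel_next(st) != ")")
      stop("selection parse error: missing ')'")
    return(mask)
  }
  sel_parse_primitive(st, model)
}

sel_is_keyword <- function(tok) {
  tolower(tok) %in% c("and", "or", "not", ")", "(", "chain", "resid",
                      "resname", "name", "element", "protein", "backbone",
                      "calpha", "all", "none")
}

sel_args <- function(st) {
  vals <- character()
  while (!is.na(sel_peek(st)) && !sel_is_keyword(sel_peek(st)))
    vals <- c(vals, sel_next(st))
  if (!length(vals))
    stop("selection parse error: keyword needs at least one argument")
  vals
}

sel_parse_primitive <- function(st, model) {
  kw <- tolower(sel_next(st))
  n <- nrow(model)
  switch(kw,
    all = rep(TRUE, n),
    none = rep(FALSE, n),
    protein = model$resname %in% AMINO3,
    backbone = model$resname %in% AMINO3 &
               model$name %in% c("N", "CA", "C", "O"),
    calpha = model$resname %in% AMINO3 & model$name == "CA",
    chain = model$chain %in% sel_args(st),
    resname = model$resname %in% toupper(sel_args(st)),
    name = model$name %in% toupper(sel_args(st)),
    element = toupper(model$element) %in% toupper(sel_args(st)),
    resid = {
      vals <- sel_args(st)
      ids <- integer()
      for (v in vals) {
        if (grepl("^-?[0-9]+:-?[0-9]+$", v)) {
          ab <- as.integer(strsplit(v, ":")[[1]])
          ids <- c(ids, seq(ab[1], ab[2]))
        } else if (grepl("^-?[0-9]+$", v)) {
          ids <- c(ids, as.integer(v))
        } else stop("selection parse error: bad resid spec '", v, "'")
      }
      model$resid %in% ids
    },
    stop("selection parse error: unknown keyword '", kw, "'")
  )
}
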