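#' Construct a topology
#'
#' A topology is the static atom table shared by all frames of a
#' trajectory: one row per atom with its name, residue and a molecule
#' class used by the analyses (`peptide`, `ion` or `water`). Waters are
#' recognised by residue name (`HOH`, `WAT`, `SOL`), the metal by residue
#' name or element in the lanthanide symbol set.
#'
#' @param name Atom names (character).
#' @param resname Residue names.
#' @param resid Residue numbers (1-based, as in the peptide sequence
#'   convention D3, N5, D7, G8, W9, E11, E14).
#' @param element Element symbols; if `NULL`, derived from the atom name
#'   (leading alphabetic characters, one- or two-letter lanthanide symbols
#'   recognised).
#' @return An object of class `ln_topology`: a data.frame with columns
#'   `index` (contiguous from 1), `name`, `resname`, `resid`, `element`,
#'   `class`.
#' @export
topology <- function(name, resname, resid, element = NULL) {
  n <- length(name)
  stopifnot(length(resname) == n, length(resid) == n)
  if (is.null(element)) element <- guess_element(name, resname)
  top <- data.frame(
    index = seq_len(n),
    name = as.character(name),
    resname = as.character(resname),
    resid = as.integer(resid),
    element = as.character(element),
    stringsAsFactors = FALSE
  )
  top$class <- classify_atoms(top)
  class(top) <- c("ln_topology", "data.frame")
  validate_topology(top)
  top
}

water_resnames <- function() c("HOH", "WAT", "SOL")

guess_element <- function(name, resname) {
  el <- sub("^([A-Za-z]+).*$", "\\1", name)
  # two-letter lanthanide names kept whole; otherwise first letter
  ln_hit <- toupper(el) %in% toupper(LN_SYMBOLS) |
    toupper(resname) %in% toupper(LN_SYMBOLS)
  out <- substr(el, 1, 1)
  out[ln_hit] <- vapply(which(ln_hit), function(i) {
    cand <- c(el[i], resname[i])
    m <- match(toupper(cand), toupper(LN_SYMBOLS))
    LN_SYMBOLS[m[!is.na(m)][1]]
  }, character(1))
  toupper(out)
}

classify_atoms <- function(top) {
  cls <- rep("peptide", nrow(top))
  cls[toupper(top$resname) %in% water_resnames()] <- "water"
  is_ion <- toupper(top$resname) %in% toupper(LN_SYMBOLS) |
    toupper(top$element) %in% toupper(LN_SYMBOLS)
  cls[is_ion] <- "ion"
  cls
}

validate_topology <- function(top) {
  if (anyDuplicated(top$index) || !identical(as.integer(top$index), seq_len(nrow(top)))) {
    stop("topology indices must be unique and contiguous")
  }
  # every water residue carries exactly one oxygen
  w <- top[top$class == "water", , drop = FALSE]
  if (nrow(w) > 0) {
    n_ox <- tapply(w$element == "O", paste(w$resname, w$resid), sum)
    if (any(n_ox != 1)) stop("every water residue must have exactly one oxygen")
  }
  invisible(top)
}

#' @export
print.ln_topology <- function(x, ...) {
  cnt <- table(x$class)
  cat("Topology:", nrow(x), "atoms (",
      paste(names(cnt), as.integer(cnt), collapse = ", "), ")\n")
  invisible(x)
}

# ---- atom selection grammar ----------------------------------------------
# expression := term ('or' term)*
# term       := factor ('and' factor)*
# factor     := 'not' factor | '(' expression ')' | keyword value
# keyword    := resid | resname | name

tokenize_selection <- function(expression) {
  expr <- gsub("\\(", " ( ", expression)
  expr <- gsub("\\)", " ) ", expr)
  toks <- strsplit(trimws(expr), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Select atoms by a boolean expression
#'
#' Resolves a minimal selection grammar against a topology. Supported
#' primaries are `resid N`, `resname X` and `name Y`, combined with
#' `and`, `or`, `not` and parentheses (precedence: `not` > `and` > `or`).
#' Matching of names is case-insensitive. An empty result is legal.
#'
#' @param top An `ln_topology`.
#' @param expression Selection text, e.g. `"resid 5 and name OD1"`.
#' @return An object of class `ln_selection`: an integer vector of sorted
#'   atom indices with the expression kept as an attribute.
#' @examples
#' top <- topology(c("LA", "OD1", "O"), c("LA", "ASN", "HOH"), c(1, 5, 100))
#' select_atoms(top, "resid 5 and name OD1")
#' @export
select_atoms <- function(top, expression) {
  stopifnot(inherits(top, "ln_topology"))
  toks <- tokenize_selection(expression)
  if (length(toks) == 0) stop("empty selection expression")
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() {
    t <- peek()
    pos <<- pos + 1L
    t
  }
  fail <- function(msg) {
    stop(sprintf("selection syntax error at token %d ('%s'): %s",
                 pos, ifelse(is.na(peek()), "<end>", peek()), msg))
  }
  parse_primary <- function() {
    kw <- advance()
    if (is.na(kw)) fail("expected a keyword")
    if (identical(kw, "(")) {
      res <- parse_expr()
      if (!identical(advance(), ")")) fail("expected ')'")
      return(res)
    }
    val <- advance()
    if (is.na(val)) fail("expected a value")
    switch(kw,
      resid = {
        v <- suppressWarnings(as.integer(val))
        if (is.na(v)) fail("resid requires an integer")
        top$resid == v
      },
      resname = toupper(top$resname) == toupper(val),
      name = toupper(top$name) == toupper(val),
      fail(sprintf("unknown keyword '%s'", kw))
    )
  }
  parse_factor <- function() {
    if (identical(peek(), "not")) {
      advance()
      return(!parse_factor())
    }
    parse_primary()
  }
  parse_term <- function() {
    res <- parse_factor()
    while (identical(peek(), "and")) {
      advance()
      res <- res & parse_factor()
    }
    res
  }
  parse_expr <- function() {
    res <- parse_term()
    while (identical(peek(), "or")) {
      advance()
      res <- res | parse_term()
    }
    res
  }
  mask <- parse_expr()
  if (pos <= length(toks)) fail("unexpected trailing tokens")
  idx <- sort(which(mask))
  structure(idx, expression = expression, class = "ln_selection")
}

#' @export
print.ln_selection <- function(x, ...) {
  cat("Selection '", attr(x, "expression"), "': ", length(x), " atom(s)\n",
      sep = "")
  invisible(x)
}

single_atom_index <- function(sel, what = "selection") {
  if (length(sel) != 1) {
    stop(what, " must resolve to exactly one atom (got ", length(sel), ")")
  }
  as.integer(sel)
}
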