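# Atom-selection mini-language. Grammar (case-insensitive keywords):
#
#   expr    := orexpr
#   orexpr  := andexpr ('or' andexpr)*
#   andexpr := notexpr ('and' notexpr)*
#   notexpr := 'not' notexpr | primary
#   primary := '(' expr ')' | 'all' | 'backbone' | 'heavy' | 'hydrogen'
#            | 'resname' LIST | 'name' LIST | 'chain' LIST
#            | 'resid' (INT ':' INT | LIST)
#
# LIST is comma-separated (no spaces needed). Selections always resolve in
# file order, so index lists are deterministic.

.backbone_names <- c("N", "CA", "C", "O", "H")  # amide H yes, HA no

.sel_tokenize <- function(expr) {
  # split on whitespace and parentheses, keep parens as tokens
  expr <- gsub("\\(", " ( ", expr)
  expr <- gsub("\\)", " ) ", expr)
  toks <- strsplit(trimws(expr), "\\s+")[[1L]]
  if (length(toks) == 0L) stop("empty selection expression")
  toks
}

.sel_parse <- function(toks) {
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  kw <- function(t) tolower(t)

  parse_or <- function() {
    node <- parse_and()
    while (!is.na(peek()) && kw(peek()) == "or") {
      take(); node <- list(op = "or", a = node, b = parse_and())
    }
    node
  }
  parse_and <- function() {
    node <- parse_not()
    while (!is.na(peek()) && kw(peek()) == "and") {
      take(); node <- list(op = "and", a = node, b = parse_not())
    }
    node
  }
  parse_not <- function() {
    if (!is.na(peek()) && kw(peek()) == "not") {
      take(); return(list(op = "not", a = parse_not()))
    }
    parse_primary()
  }
  parse_primary <- function() {
    t <- take()
    if (is.na(t)) stop("unexpected end of selection expression")
    switch(kw(t),
      "(" = {
        node <- parse_or()
        if (is.na(peek()) || take() != ")") stop("missing ')' in selection")
        node
      },
      "all" = list(op = "all"),
      "backbone" = list(op = "backbone"),
      "heavy" = list(op = "heavy"),
      "hydrogen" = list(op = "hydrogen"),
      "resname" = list(op = "resname", args = strsplit(take(), ",")[[1L]]),
      "name" = list(op = "name", args = strsplit(take(), ",")[[1L]]),
      "chain" = list(op = "chain", args = strsplit(take(), ",")[[1L]]),
      "resid" = {
        arg <- take()
        if (grepl(":", arg, fixed = TRUE)) {
          r <- as.integer(strsplit(arg, ":", fixed = TRUE)[[1L]])
          if (length(r) != 2L || anyNA(r)) stop("bad resid range: ", arg)
          list(op = "resid", args = seq(r[1L], r[2L]))
        } else {
          v <- as.integer(strsplit(arg, ",")[[1L]])
          if (anyNA(v)) stop("bad resid list: ", arg)
          list(op = "resid", args = v)
        }
      },
      stop("unknown selection token: ", t)
    )
  }

  node <- parse_or()
  if (!is.na(peek())) stop("trailing tokens in selection: ", peek())
  node
}

.sel_eval <- function(node, atoms) {
  switch(node$op,
    all = rep(TRUE, nrow(atoms)),
    backbone = atoms$name %in% .backbone_names,
    heavy = toupper(atoms$element) != "H",
    hydrogen = toupper(atoms$element) == "H",
    resname = atoms$resname %in% trimws(node$args),
    name = atoms$name %in% trimws(node$args),
    chain = atoms$chain %in% trimws(node$args),
    resid = atoms$resid %in% node$args,
    and = .sel_eval(node$a, atoms) & .sel_eval(node$b, atoms),
    or = .sel_eval(node$a, atoms) | .sel_eval(node$b, atoms),
    not = !.sel_eval(node$a, atoms),
    stop("bad selection node")
  )
}

#' Resolve a selection expression to atom indices
#'
#' @param s a `csg_structure` or `csg_trajectory`.
#' @param expression selection string, e.g. `"backbone"`, `"resname CSG"`,
#'   `"resid 2:5 and not hydrogen"`, `"name CA,CB or name SG"`.
#' @return increasing 1-based atom index vector (file order); an empty result
#'   is a hard error naming the expression.
#' @examples
#' s <- make_toy_peptide("AA")
#' select_atoms(s, "backbone")
#' @export
select_atoms <- function(s, expression) {
  if (inherits(s, "csg_trajectory")) s <- s$topology
  stopifnot(inherits(s, "csg_structure"))
  node <- .sel_parse(.sel_tokenize(expression))
  idx <- which(.sel_eval(node, s$atoms))
  if (length(idx) == 0L) {
    stop("selection matched no atoms: \"", expression, "\"")
  }
  idx
}
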