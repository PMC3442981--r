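#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules link genes to reactions with boolean logic: OR encodes
#' isozymes (any one gene suffices), AND encodes complex subunits (all
#' are required). The grammar accepts gene identifiers matching
#' \code{[A-Za-z0-9_.-]+}, parentheses, and case-insensitive
#' \code{and} / \code{or} connectives. An empty rule means the reaction
#' is always catalysed ("always on").
#'
#' @param rule_text character(1) rule, e.g. \code{"(ADH1 or ADH3 or ADH5)"}.
#' @return An expression tree of class \code{"gpr"}: a nested list with
#'   element \code{op} one of \code{"gene"}, \code{"and"}, \code{"or"},
#'   \code{"true"}; gene nodes carry \code{gene}, connective nodes carry
#'   \code{args} (a list of subtrees).
#' @examples
#' e <- parseGPR("ADH1 or ADH3 or ADH5")
#' evaluateGPR(e, deleted_genes = c("ADH1", "ADH3"))
#' @export
parseGPR <- function(rule_text) {
  if (is.null(rule_text) || length(rule_text) == 0L || is.na(rule_text))
    rule_text <- ""
  stopifnot(is.character(rule_text), length(rule_text) == 1L)
  toks <- gprTokenize(rule_text)
  if (nrow(toks) == 0L)
    return(structure(list(op = "true"), class = "gpr"))
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  st$open <- integer()   # positions of currently open parentheses
  expr <- gprParseOr(st, rule_text)
  if (st$pos <= nrow(st$toks))
    stop(sprintf("GPR parse error at position %d in rule '%s': unexpected '%s'",
                 st$toks$start[st$pos], rule_text, st$toks$text[st$pos]),
         call. = FALSE)
  structure(expr, class = "gpr")
}

gprTokenize <- function(text) {
  pat <- "\\(|\\)|[A-Za-z0-9_.-]+"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1L)
    toks <- data.frame(text = character(), start = integer())
  else
    toks <- data.frame(text = regmatches(text, gregexpr(pat, text))[[1]],
                       start = as.integer(m))
  # anything not matched and not whitespace is illegal
  residue <- gsub(pat, " ", text)
  bad <- regexpr("[^[:space:]]", residue)
  if (bad > 0L)
    stop(sprintf("GPR parse error at position %d in rule '%s': illegal character '%s'",
                 bad, text, substr(residue, bad, bad)), call. = FALSE)
  toks
}

gprPeek <- function(st) {
  if (st$pos > nrow(st$toks)) NULL else st$toks$text[st$pos]
}

gprParseOr <- function(st, rule) {
  args <- list(gprParseAnd(st, rule))
  while (!is.null(tk <- gprPeek(st)) && tolower(tk) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gprParseAnd(st, rule)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
}

gprParseAnd <- function(st, rule) {
  args <- list(gprParseAtom(st, rule))
  while (!is.null(tk <- gprPeek(st)) && tolower(tk) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gprParseAtom(st, rule)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
}

gprParseAtom <- function(st, rule) {
  tk <- gprPeek(st)
  if (is.null(tk)) {
    if (length(st$open))
      stop(sprintf("GPR parse error at position %d in rule '%s': unclosed parenthesis",
                   st$open[length(st$open)], rule), call. = FALSE)
    stop(sprintf("GPR parse error at end of rule '%s': expected gene or '('",
                 rule), call. = FALSE)
  }
  start <- st$toks$start[st$pos]
  if (tk == "(") {
    st$open <- c(st$open, start)
    st$pos <- st$pos + 1L
    inner <- gprParseOr(st, rule)
    cl <- gprPeek(st)
    if (is.null(cl) || cl != ")")
      stop(sprintf("GPR parse error at position %d in rule '%s': unclosed parenthesis",
                   start, rule), call. = FALSE)
    st$open <- st$open[-length(st$open)]
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk == ")" || tolower(tk) %in% c("and", "or"))
    stop(sprintf("GPR parse error at position %d in rule '%s': unexpected '%s'",
                 start, rule, tk), call. = FALSE)
  st$pos <- st$pos + 1L
  list(op = "gene", gene = tk)
}

#' Evaluate a GPR expression under a set of gene deletions
#'
#' Deleted genes are assigned FALSE, all other genes TRUE; the expression
#' is evaluated with standard boolean semantics. An always-on (empty)
#' expression is TRUE under every deletion set.
#'
#' @param expr a \code{"gpr"} expression from [parseGPR()].
#' @param deleted_genes character vector of deleted gene ids.
#' @return logical(1): is the reaction still active?
#' @export
evaluateGPR <- function(expr, deleted_genes = character()) {
  switch(expr$op,
    true = TRUE,
    gene = !(expr$gene %in% deleted_genes),
    and  = all(vapply(expr$args, evaluateGPR, logical(1), deleted_genes)),
    or   = any(vapply(expr$args, evaluateGPR, logical(1), deleted_genes)),
    stop("malformed GPR node: ", expr$op))
}

#' @rdname parseGPR
#' @param x,... a \code{"gpr"} expression (method for \code{format}/\code{print}).
#' @method format gpr
#' @export
format.gpr <- function(x, ...) gprDeparse(x, parent = "")

#' @method print gpr
#' @export
print.gpr <- function(x, ...) {
  cat("<gpr> ", if (x$op == "true") "(always on)" else format(x), "\n", sep = "")
  invisible(x)
}

gprDeparse <- function(node, parent) {
  switch(node$op,
    true = "",
    gene = node$gene,
    {
      parts <- vapply(node$args, gprDeparse, character(1), parent = node$op)
      s <- paste(parts, collapse = paste0(" ", node$op, " "))
      # parenthesize OR under AND so precedence survives reparsing
      if (parent == "and" && node$op == "or") paste0("(", s, ")") else s
    })
}

#' Genes referenced by a GPR expression
#' @param expr a \code{"gpr"} expression.
#' @return character vector of distinct gene ids (empty for always-on).
#' @export
gprGenes <- function(expr) {
  switch(expr$op,
    true = character(),
    gene = expr$gene,
    unique(unlist(lapply(expr$args, gprGenes))))
}

#' Disjunctive normal form of a GPR expression
#'
#' Each conjunct is one minimal way of keeping the reaction active (a set
#' of genes that must all be present). Supersets of other conjuncts are
#' pruned, so the result lists the irredundant enzyme alternatives.
#'
#' @param expr a \code{"gpr"} expression.
#' @return list of character vectors (sorted gene sets); \code{list()} for
#'   always-on.
#' @export
gprToDNF <- function(expr) {
  conj <- gprDNFRec(expr)
  conj <- lapply(conj, function(s) sort(unique(s)))
  pruneSupersets(unique(conj))
}

gprDNFRec <- function(node) {
  switch(node$op,
    true = list(),
    gene = list(node$gene),
    or   = unlist(lapply(node$args, gprDNFRec), recursive = FALSE),
    and  = {
      parts <- lapply(node$args, gprDNFRec)
      acc <- list(character())
      for (p in parts) {
        if (length(p) == 0L) next  # always-on factor
        acc <- unlist(lapply(acc, function(a) lapply(p, function(b) c(a, b))),
                      recursive = FALSE)
      }
      acc
    })
}

pruneSupersets <- function(sets) {
  if (length(sets) <= 1L) return(sets)
  ord <- order(lengths(sets))
  sets <- sets[ord]
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) {
    if (!keep[i]) next
    for (j in seq_along(sets)) {
      if (j <= i || !keep[j]) next
      if (all(sets[[i]] %in% sets[[j]])) keep[j] <- FALSE
    }
  }
  sets[keep]
}

#' Minimal gene deletion sets disabling a group of reactions
#'
#' Finds every inclusion-minimal set of genes whose deletion switches off
#' all the listed reactions (their GPRs evaluate FALSE), and reports which
#' other reactions each set disables as a side effect. Disabling a
#' reaction requires hitting every DNF conjunct of its GPR, so the answer
#' is the set of minimal hitting sets over the pooled conjuncts.
#' Exhaustive subset search is used when at most \code{exhaustive_limit}
#' genes are involved; above that a minimum-cardinality hitting set is
#' found by implicit enumeration and alternatives of that cardinality are
#' collected.
#'
#' @param model a [MetabolicModel-class].
#' @param reactions_to_disable character vector of reaction ids; each must
#'   carry a non-empty GPR.
#' @param exhaustive_limit integer; gene-count threshold for exhaustive
#'   search (default 12).
#' @return A list of records, ordered by set size then lexicographically;
#'   each has \code{genes} (character), \code{side_effects} (other
#'   reaction ids also disabled). Empty input gives an empty-set record.
#' @export
minimalGeneKnockouts <- function(model, reactions_to_disable,
                                 exhaustive_limit = 12L) {
  reactions_to_disable <- as.character(reactions_to_disable)
  if (length(reactions_to_disable) == 0L)
    return(list(list(genes = character(), side_effects = character())))
  idx <- match(reactions_to_disable, reactionIds(model))
  if (anyNA(idx))
    stop("unknown reaction id(s): ",
         paste(reactions_to_disable[is.na(idx)], collapse = ", "))
  exprs <- lapply(reactions_to_disable, function(r) gprOf(model, r))
  empty <- vapply(exprs, function(e) e$op == "true", logical(1))
  if (any(empty))
    stop("reaction(s) not gene-disableable (empty GPR): ",
         paste(reactions_to_disable[empty], collapse = ", "))
  conjuncts <- unique(unlist(lapply(exprs, gprToDNF), recursive = FALSE))
  genes <- sort(unique(unlist(conjuncts)))
  hits <-
    if (length(genes) <= exhaustive_limit)
      minimalHittingSetsExhaustive(conjuncts, genes)
    else
      minimalHittingSetsBranch(conjuncts, genes)
  # deterministic order: size, then lexicographic on the joined gene list
  key <- vapply(hits, function(s) paste(s, collapse = "\r"), character(1))
  hits <- hits[order(lengths(hits), key)]
  others <- setdiff(reactionIds(model), reactions_to_disable)
  lapply(hits, function(gs) {
    off <- others[!vapply(others, function(r)
      evaluateGPR(gprOf(model, r), gs), logical(1))]
    list(genes = gs, side_effects = off)
  })
}

# All inclusion-minimal hitting sets by exhaustive subset enumeration.
minimalHittingSetsExhaustive <- function(conjuncts, genes) {
  n <- length(genes)
  found <- list()
  for (k in seq_len(n)) {
    combs <- utils::combn(genes, k, simplify = FALSE)
    for (s in combs) {
      if (any(vapply(found, function(f) all(f %in% s), logical(1)))) next
      if (all(vapply(conjuncts, function(cj) any(cj %in% s), logical(1))))
        found <- c(found, list(s))
    }
    # once every conjunct is hit by some found set of size <= k we can
    # still discover incomparable larger minimal sets, so no early exit
  }
  found
}

# Minimum-cardinality hitting sets by depth-first implicit enumeration
# (branch on the genes of the first un-hit conjunct).
minimalHittingSetsBranch <- function(conjuncts, genes) {
  best <- new.env(parent = emptyenv())
  best$size <- Inf
  best$sets <- list()
  recurse <- function(chosen) {
    if (length(chosen) > best$size) return()
    unhit <- conjuncts[!vapply(conjuncts, function(cj) any(cj %in% chosen),
                               logical(1))]
    if (length(unhit) == 0L) {
      s <- sort(chosen)
      if (length(s) < best$size) {
        best$size <- length(s)
        best$sets <- list(s)
      } else if (length(s) == best$size &&
                 !any(vapply(best$sets, identical, logical(1), s))) {
        best$sets <- c(best$sets, list(s))
      }
      return()
    }
    if (length(chosen) >= best$size) return()
    for (g in unhit[[1]]) recurse(c(chosen, g))
  }
  recurse(character())
  best$sets
}
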