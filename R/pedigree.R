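#' Construct a pedigree object
#'
#' A pedigree is a data.frame with one row per individual and columns
#' `family`, `id`, `father`, `mother` (`NA` = unknown parent), `sex`
#' (`"male"`, `"female"`, `"unknown"`), `phenotype` (`"affected"`,
#' `"unaffected"`, `"uncertain"`, `"untested"`) and `sequenced` (logical:
#' member of the exome-sequenced subset). Structural invariants (unique ids,
#' referential integrity of parent links, acyclicity) are enforced at
#' construction.
#'
#' @param individuals data.frame with at least columns `id`, `father`,
#'   `mother`, `sex`, `phenotype`; optional `family` and `sequenced`.
#' @param name pedigree name (defaults to the first `family` value).
#' @return an object of class `pedigree`.
#' @export
pedigree <- function(individuals, name = NULL) {
  df <- as.data.frame(individuals, stringsAsFactors = FALSE)
  required <- c("id", "father", "mother", "sex", "phenotype")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop_user("pedigree: missing column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(df$family)) df$family <- name %||% "FAM1"
  if (is.null(df$sequenced)) df$sequenced <- FALSE
  df$sequenced <- as.logical(df$sequenced)
  df$id <- as.character(df$id)
  df$father <- as.character(df$father)
  df$mother <- as.character(df$mother)
  df$father[df$father %in% c("0", "", NA)] <- NA_character_
  df$mother[df$mother %in% c("0", "", NA)] <- NA_character_

  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup))
    stop_user("pedigree: duplicate individual id(s): ", paste(dup, collapse = ", "))
  if (!all(df$sex %in% c("male", "female", "unknown")))
    stop_user("pedigree: invalid sex value(s)")
  if (!all(df$phenotype %in% PHENOTYPE_LEVELS))
    stop_user("pedigree: invalid phenotype value(s)")

  for (col in c("father", "mother")) {
    bad <- setdiff(stats::na.omit(df[[col]]), df$id)
    if (length(bad))
      stop_user("pedigree: ", col, " id(s) not present in pedigree: ",
                paste(bad, collapse = ", "))
  }
  if (is.null(topo_order(df)))
    stop_user("pedigree: parent links contain a cycle (an individual is its own ancestor)")

  df <- df[, c("family", "id", "father", "mother", "sex", "phenotype", "sequenced")]
  rownames(df) <- NULL
  structure(df, class = c("pedigree", "data.frame"),
            name = name %||% df$family[1])
}

# Kahn topological order over parent->child edges; NULL if cyclic.
topo_order <- function(df) {
  ids <- df$id
  parents <- lapply(seq_len(nrow(df)), function(i)
    stats::na.omit(c(df$father[i], df$mother[i])))
  indeg <- vapply(parents, length, 1L)
  names(indeg) <- ids
  children <- split(
    rep(ids, vapply(parents, length, 1L)),
    unlist(parents, use.names = FALSE)
  )
  queue <- ids[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (ch in children[[v]] %||% character(0)) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != length(ids)) NULL else out
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree '%s': %d individuals, %d affected, %d sequenced>\n",
              attr(x, "name"), nrow(x), sum(x$phenotype == "affected"),
              sum(x$sequenced)))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Parse a PED-like pedigree file
#'
#' Whitespace-delimited text, `#` comment lines ignored. Columns: family, id,
#' father, mother, sex, phenotype, and an optional seventh 0/1 column
#' flagging exome-sequenced individuals. Codes: parent `0` = unknown; sex
#' 1 = male, 2 = female, 0 = unknown; phenotype 1 = unaffected, 2 = affected,
#' 0 = untested, 9 = uncertain. Code 9 extends the standard dialect because
#' uncertain diagnoses must stay distinguishable from untested individuals
#' even though both are unconstrained during filtering.
#'
#' @param path path to the file.
#' @return a [pedigree()] object.
#' @export
parse_ped <- function(path) {
  if (!file.exists(path)) stop_user("parse_ped: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop_user("parse_ped: no data rows in ", path)
  fields <- strsplit(lines, "[ \t]+")
  ncol <- lengths(fields)
  if (any(ncol < 6))
    stop_user("parse_ped: line with fewer than 6 columns in ", path)
  mat <- t(vapply(fields, function(f) f[1:7][1:7], character(7)))
  sex_map <- c("1" = "male", "2" = "female", "0" = "unknown")
  phe_map <- c("1" = "unaffected", "2" = "affected", "0" = "untested",
               "9" = "uncertain")
  sex <- sex_map[mat[, 5]]
  phe <- phe_map[mat[, 6]]
  if (anyNA(sex)) stop_user("parse_ped: invalid sex code(s): ",
                            paste(unique(mat[is.na(sex), 5]), collapse = ", "))
  if (anyNA(phe)) stop_user("parse_ped: invalid phenotype code(s): ",
                            paste(unique(mat[is.na(phe), 6]), collapse = ", "))
  seq_flag <- ifelse(is.na(mat[, 7]), "0", mat[, 7]) == "1"
  df <- data.frame(family = mat[, 1], id = mat[, 2], father = mat[, 3],
                   mother = mat[, 4], sex = unname(sex), phenotype = unname(phe),
                   sequenced = seq_flag, stringsAsFactors = FALSE)
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup))
    stop_user("parse_ped: duplicate individual id(s): ", paste(dup, collapse = ", "))
  pedigree(df, name = df$family[1])
}

#' Write a pedigree back to PED-like text
#'
#' Inverse of [parse_ped()]; `parse_ped(write_ped(ped, f))` reproduces `ped`
#' exactly (modulo whitespace normalization).
#'
#' @param ped a pedigree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  sex_code <- c(male = "1", female = "2", unknown = "0")
  phe_code <- c(unaffected = "1", affected = "2", untested = "0", uncertain = "9")
  lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%s",
                   ped$family, ped$id,
                   ifelse(is.na(ped$father), "0", ped$father),
                   ifelse(is.na(ped$mother), "0", ped$mother),
                   sex_code[ped$sex], phe_code[ped$phenotype],
                   ifelse(ped$sequenced, "1", "0"))
  writeLines(lines, path)
  invisible(path)
}

#' Partition individuals by phenotype constraint
#'
#' Splits a subset of the pedigree into the affected, the unaffected, and the
#' unconstrained (uncertain or untested) — the three roles individuals play
#' in co-segregation filtering: affected must carry, unaffected must not,
#' and the rest impose no constraint.
#'
#' @param ped a pedigree.
#' @param subset character vector of ids, or `"all"`.
#' @return list with character-vector elements `affected`, `unaffected`,
#'   `unconstrained`; always a disjoint partition of `subset`.
#' @export
phenotype_groups <- function(ped, subset = "all") {
  stopifnot(inherits(ped, "pedigree"))
  ids <- if (identical(subset, "all")) ped$id else as.character(subset)
  unknown <- setdiff(ids, ped$id)
  if (length(unknown))
    stop_user("phenotype_groups: unknown id(s): ", paste(unknown, collapse = ", "))
  phe <- ped$phenotype[match(ids, ped$id)]
  list(affected = ids[phe == "affected"],
       unaffected = ids[phe == "unaffected"],
       unconstrained = ids[phe %in% c("uncertain", "untested")])
}

#' Structural warnings for a pedigree
#'
#' Non-fatal checks: individuals with exactly one known parent, parent roles
#' inconsistent with recorded sex (a father who is recorded female, or a
#' mother recorded male), and disconnected family components. Structural
#' errors (duplicate ids, dangling parents, cycles) are raised at parse time
#' instead.
#'
#' @param ped a pedigree.
#' @return character vector of warnings (possibly empty); never mutates input.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  warnings <- character(0)
  single <- xor(is.na(ped$father), is.na(ped$mother))
  for (id in ped$id[single])
    warnings <- c(warnings, sprintf("single known parent for individual '%s'", id))
  for (i in seq_len(nrow(ped))) {
    f <- ped$father[i]; m <- ped$mother[i]
    if (!is.na(f) && ped$sex[match(f, ped$id)] == "female")
      warnings <- c(warnings, sprintf(
        "father '%s' of '%s' is recorded as female", f, ped$id[i]))
    if (!is.na(m) && ped$sex[match(m, ped$id)] == "male")
      warnings <- c(warnings, sprintf(
        "mother '%s' of '%s' is recorded as male", m, ped$id[i]))
  }
  comp <- ped_components(ped)
  if (max(comp) > 1L)
    warnings <- c(warnings, sprintf("pedigree has %d disconnected components",
                                    max(comp)))
  warnings
}

# union-find over parent-child edges
ped_components <- function(ped) {
  parent <- seq_len(nrow(ped))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }
  idx <- function(id) match(id, ped$id)
  for (i in seq_len(nrow(ped))) {
    if (!is.na(ped$father[i])) union2(i, idx(ped$father[i]))
    if (!is.na(ped$mother[i])) union2(i, idx(ped$mother[i]))
  }
  roots <- vapply(seq_len(nrow(ped)), find, 1L)
  as.integer(factor(roots))
}

# --- small query helpers used across modules ---------------------------

ped_parents <- function(ped, id) {
  i <- match(id, ped$id)
  if (is.na(i)) stop_user("unknown individual: ", id)
  stats::na.omit(c(ped$father[i], ped$mother[i]))
}

ped_children <- function(ped, id) {
  ped$id[!is.na(ped$father) & ped$father == id |
         !is.na(ped$mother) & ped$mother == id]
}

ped_is_founder <- function(ped, id) length(ped_parents(ped, id)) == 0L

ped_sequenced_ids <- function(ped) ped$id[ped$sequenced]
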