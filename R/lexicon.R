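#' Lexical-semantic connectivity for a list of unrelated words
#'
#' Each entry of the binary lexical-semantic matrix is set to one
#' independently with probability `p_conn` (default 16%), so a lexical
#' unit is represented by `n_sem * p_conn` semantic features on average
#' (7.2 with the default sizes).  The coupling is symmetric: the same
#' matrix is used in both directions.
#'
#' @param params A [can_params].
#' @param seed Optional integer seed; identical seeds give identical
#'   lexica.
#' @param n_items Number of lexical units that serve as list items
#'   (defaults to `params$n_list`); the remaining units are potential
#'   intrusion sources.
#' @return An object of class `can_lexicon`: list with `W_xy` (binary
#'   `n_lex x n_sem` matrix), `items` (lexical indices of the list items),
#'   `category_of` (per-unit category label, `NA` for unrelated/filler
#'   units), `shared_features` (named list of per-category feature index
#'   sets) and `seed`.
#' @export
build_unrelated_lexicon <- function(params, seed = NULL,
                                    n_items = params$n_list) {
  if (params$p_conn < 0 || params$p_conn > 1)
    stop("p_conn must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(stats::rbinom(params$n_lex * params$n_sem, 1L, params$p_conn),
              params$n_lex, params$n_sem)
  structure(list(W_xy = W,
                 items = seq_len(n_items),
                 category_of = rep(NA_character_, params$n_lex),
                 shared_features = list(),
                 seed = seed),
            class = "can_lexicon")
}

#' Lexical-semantic connectivity for categorized word lists
#'
#' Members of a category share a dedicated band of `n_shared` semantic
#' features (all set to one), plus item-specific distinctive features
#' drawn independently with probability `p_conn` outside every category
#' band.  Category bands are disjoint, assigned consecutively from feature
#' 1.  Non-item lexical units (potential intrusion sources) receive random
#' features outside the bands, so category structure is unique to list
#' items.
#'
#' @param categories Named integer vector giving the number of items per
#'   category, e.g. `c(a = 4, b = 4, c = 4, d = 4)`.
#' @inheritParams build_unrelated_lexicon
#' @return A `can_lexicon` (see [build_unrelated_lexicon()]); item lexical
#'   indices run consecutively category by category.
#' @examples
#' p <- can_params()
#' lex <- build_category_lexicon(c(main = 11, isolate = 1), p, seed = 1)
#' table(lex$category_of[lex$items])
#' @export
build_category_lexicon <- function(categories, params, seed = NULL) {
  if (is.null(names(categories)) || any(!nzchar(names(categories))))
    stop("categories must be a named vector of item counts", call. = FALSE)
  n_cat_groups <- length(categories)
  n_items <- sum(categories)
  if (n_items > params$n_lex)
    stop("more items than lexical units", call. = FALSE)
  need <- n_cat_groups * params$n_shared
  if (need > params$n_sem)
    stop("category shared-feature bands exceed n_sem (bands must be disjoint)",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  bands <- lapply(seq_len(n_cat_groups) - 1L,
                  function(k) k * params$n_shared + seq_len(params$n_shared))
  names(bands) <- names(categories)
  free_features <- setdiff(seq_len(params$n_sem), unlist(bands))
  W <- matrix(0L, params$n_lex, params$n_sem)
  # distinctive/filler features: the same 16% rate, outside all bands
  W[, free_features] <-
    matrix(stats::rbinom(params$n_lex * length(free_features), 1L,
                         params$p_conn),
           params$n_lex, length(free_features))
  category_of <- rep(NA_character_, params$n_lex)
  row <- 0L
  for (ci in seq_len(n_cat_groups)) {
    for (j in seq_len(categories[[ci]])) {
      row <- row + 1L
      W[row, bands[[ci]]] <- 1L
      category_of[row] <- names(categories)[ci]
    }
  }
  structure(list(W_xy = W,
                 items = seq_len(n_items),
                 category_of = category_of,
                 shared_features = bands,
                 seed = seed),
            class = "can_lexicon")
}

new_study_list <- function(items, categories, design,
                           isolate_position = NA_integer_,
                           critical_position = NA_integer_) {
  if (anyDuplicated(items)) stop("duplicate item in study list", call. = FALSE)
  structure(list(items = as.integer(items),
                 categories = as.character(categories),
                 design = design,
                 isolate_position = as.integer(isolate_position),
                 critical_position = as.integer(critical_position)),
            class = "can_study_list")
}

#' @export
print.can_study_list <- function(x, ...) {
  cat("<can_study_list> design =", x$design, "(", length(x$items), "items )\n")
  lab <- paste0(x$categories, x$items)
  if (!is.na(x$isolate_position)) lab[x$isolate_position] <-
    paste0("[", lab[x$isolate_position], "]")
  cat(" ", paste(lab, collapse = " "), "\n")
  invisible(x)
}

#' CVLT-like categorized study list
#'
#' Samples a presentation order for a 4-category x 4-item lexicon (or any
#' categorized lexicon): a uniformly random permutation of all items
#' subject to the constraint that no two consecutive items come from the
#' same category.  Rejection sampling over uniform permutations gives
#' exact uniformity on the constrained support.  The order differs from
#' run to run.
#'
#' @param lexicon A categorized `can_lexicon`.
#' @param seed Optional integer seed.
#' @param max_tries Rejection-sampling cap (the constraint is easily
#'   satisfiable for the CVLT design).
#' @return A `can_study_list` with `design = "cvlt"`.
#' @export
make_cvlt_list <- function(lexicon, seed = NULL, max_tries = 10000L) {
  cats <- lexicon$category_of[lexicon$items]
  if (anyNA(cats)) stop("lexicon has uncategorized items", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(max_tries)) {
    ord <- sample(length(lexicon$items))
    if (!any(cats[ord][-1] == cats[ord][-length(ord)])) {
      return(new_study_list(lexicon$items[ord], cats[ord], "cvlt"))
    }
  }
  stop("could not satisfy the no-adjacent-same-category constraint",
       call. = FALSE)
}

#' Von Restorff (isolate) study list
#'
#' Builds a list in which every item but one belongs to the main category
#' and a single isolate from a different category occupies the requested
#' serial position.  The lexicon must contain a main category with
#' `n - 1` items and an isolate category with one item (see
#' [build_category_lexicon()]).
#'
#' @param lexicon A `can_lexicon` with exactly two categories, one of them
#'   a singleton.
#' @param isolate_position 1-based serial position of the isolate.
#' @return A `can_study_list` with `design = "von_restorff"`.
#' @export
make_vr_list <- function(lexicon, isolate_position) {
  cats <- lexicon$category_of[lexicon$items]
  tab <- table(cats)
  if (length(tab) != 2L || min(tab) != 1L)
    stop("lexicon must have one main category and a single isolate",
         call. = FALSE)
  n <- length(lexicon$items)
  if (!is.numeric(isolate_position) || isolate_position < 1 ||
      isolate_position > n)
    stop("isolate_position out of range 1..", n, call. = FALSE)
  iso_cat <- names(tab)[tab == 1L]
  iso_item <- lexicon$items[cats == iso_cat]
  main_items <- lexicon$items[cats != iso_cat]
  items <- append(main_items, iso_item, after = isolate_position - 1L)
  new_study_list(items, lexicon$category_of[items], "von_restorff",
                 isolate_position = isolate_position,
                 critical_position = isolate_position)
}

#' Same-category baseline study list
#'
#' The control for the Von Restorff design: the critical serial position
#' is occupied by an item of the *same* category as the rest of the list
#' (the entire list shares one set of category features), so the critical
#' item is not distinctive.  The lexicon must contain a single category
#' covering all items.
#'
#' @param lexicon A single-category `can_lexicon`.
#' @param critical_position 1-based serial position of the measured item.
#' @return A `can_study_list` with `design = "same_category"`.
#' @export
make_same_category_list <- function(lexicon, critical_position) {
  cats <- lexicon$category_of[lexicon$items]
  if (anyNA(cats) || length(unique(cats)) != 1L)
    stop("lexicon must contain a single category covering all items",
         call. = FALSE)
  n <- length(lexicon$items)
  if (critical_position < 1 || critical_position > n)
    stop("critical_position out of range 1..", n, call. = FALSE)
  new_study_list(lexicon$items, cats, "same_category",
                 critical_position = critical_position)
}

#' Unrelated study list
#'
#' All items carry independent random semantic features (no shared
#' category structure); used to probe buffer capacity and as a baseline.
#'
#' @param lexicon An uncategorized `can_lexicon`
#'   (see [build_unrelated_lexicon()]).
#' @return A `can_study_list` with `design = "unrelated"`.
#' @export
make_unrelated_list <- function(lexicon) {
  new_study_list(lexicon$items, rep(NA_character_, length(lexicon$items)),
                 "unrelated")
}

#' Export a lexicon as CSV
#'
#' Writes one row per lexical unit: item id, category label and the
#' indices of its semantic features.  The generating seed is recorded in a
#' `#` header line.
#'
#' @param lexicon A `can_lexicon`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_lexicon <- function(lexicon, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# can_lexicon seed=",
                    if (is.null(lexicon$seed)) "NA" else lexicon$seed), con)
  df <- data.frame(
    unit = seq_len(nrow(lexicon$W_xy)),
    is_item = seq_len(nrow(lexicon$W_xy)) %in% lexicon$items,
    category = lexicon$category_of,
    features = apply(lexicon$W_xy, 1, function(r) paste(which(r == 1),
                                                        collapse = " "))
  )
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
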