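#' Tokenize tweets into mining transactions
#'
#' Text preparation for frequent itemset mining: punctuation is replaced by
#' spaces, the text is lowercased and split on whitespace, stopwords are
#' removed, and tokens are deduplicated — so each tweet becomes a set of
#' distinct content tokens (one "transaction").
#'
#' @param text Character vector of tweet texts.
#' @param stopwords Stopwords to drop (lowercase).
#' @return A list of character vectors, one token set per input text.
#' @examples
#' tokenize_transactions("I quit vaping, quit!", stopwords = "i")
#' @export
tokenize_transactions <- function(text, stopwords = default_stopwords()) {
  toks <- stringr::str_split(normalize_text(text), stringr::fixed(" "))
  lapply(toks, function(t) {
    unique(t[nzchar(t) & !(t %in% stopwords)])
  })
}

#' Mine frequent itemsets with FP-growth
#'
#' From-scratch FP-growth: transactions are compressed into a frequent-
#' pattern tree whose paths share prefixes (items ordered by descending
#' global support, ties broken lexicographically), and itemsets are mined
#' recursively from per-item conditional trees, avoiding the candidate
#' generation of Apriori. Support is the absolute number of transactions
#' containing the itemset.
#'
#' @param transactions List of character vectors (token sets), e.g. from
#'   [tokenize_transactions()].
#' @param min_support Minimum absolute support (transaction count), >= 1.
#' @return A tibble with columns `items` (list of sorted character
#'   vectors), `size`, and `support`, ordered by size then descending
#'   support. Exactly the itemsets with support >= `min_support`.
#' @examples
#' tr <- list(c("a", "b"), c("b", "c"), c("a", "b", "c"), "b")
#' mine_frequent_itemsets(tr, min_support = 2)
#' @export
mine_frequent_itemsets <- function(transactions, min_support) {
  if (min_support < 1) {
    rlang::abort("`min_support` must be >= 1.")
  }
  acc <- new.env(parent = emptyenv())
  acc$items <- vector("list", 64L)
  acc$support <- numeric(64L)
  acc$k <- 0L
  fpg_mine(transactions, rep(1, length(transactions)), min_support,
           character(), acc)
  if (acc$k == 0L) {
    return(tibble::tibble(
      items = list(), size = integer(), support = numeric()
    ))
  }
  items <- acc$items[seq_len(acc$k)]
  out <- tibble::tibble(
    items = items,
    size = lengths(items),
    support = acc$support[seq_len(acc$k)]
  )
  key <- vapply(out$items, paste, character(1), collapse = " ")
  out[order(out$size, -out$support, key), ]
}

fpg_record <- function(acc, itemset, support) {
  k <- acc$k + 1L
  if (k > length(acc$support)) {  # grow by doubling
    length(acc$items) <- 2L * k
    length(acc$support) <- 2L * k
  }
  acc$items[[k]] <- itemset
  acc$support[k] <- support
  acc$k <- k
}

# Recursive miner over weighted (conditional) transactions. `weights` are
# path counts from the parent tree; at the top level all 1.
fpg_mine <- function(trans, weights, min_support, suffix, acc) {
  if (length(trans) == 0) {
    return(invisible())
  }
  flat <- unlist(trans, use.names = FALSE)
  if (length(flat) == 0) {
    return(invisible())
  }
  supp <- vapply(
    split(rep.int(weights, lengths(trans)), flat), sum, numeric(1)
  )
  supp <- supp[supp >= min_support]
  if (length(supp) == 0) {
    return(invisible())
  }
  for (it in names(supp)) {
    fpg_record(acc, sort(c(it, suffix)), supp[[it]])
  }
  # FP-tree item order: descending support, ties lexicographic
  ordered <- names(supp)[order(-supp, names(supp))]
  rank <- stats::setNames(seq_along(ordered), ordered)
  ftrans <- lapply(trans, function(t) {
    t <- t[t %in% ordered]
    t[order(rank[t])]
  })
  keep <- lengths(ftrans) > 0
  tree <- build_fp_tree(ftrans[keep], weights[keep])
  # mine conditional trees, least frequent item first
  for (it in rev(ordered)) {
    nodes <- which(tree$item == it)
    cond <- vector("list", length(nodes))
    cond_w <- numeric(length(nodes))
    m <- 0L
    for (nd in nodes) {
      path <- character()
      p <- tree$parent[nd]
      while (p > 0L) {
        path <- c(tree$item[p], path)
        p <- tree$parent[p]
      }
      if (length(path) > 0) {
        m <- m + 1L
        cond[[m]] <- path
        cond_w[m] <- tree$count[nd]
      }
    }
    if (m > 0L) {
      fpg_mine(cond[seq_len(m)], cond_w[seq_len(m)], min_support,
               c(it, suffix), acc)
    }
  }
  invisible()
}

# Prefix tree over rank-ordered transactions; nodes as parallel vectors,
# child lookup hashed on (parent id, item).
build_fp_tree <- function(trans, weights) {
  item <- character()
  count <- numeric()
  parent <- integer()
  children <- new.env(hash = TRUE, parent = emptyenv())
  n <- 0L
  for (j in seq_along(trans)) {
    cur <- 0L
    wj <- weights[j]
    for (it in trans[[j]]) {
      key <- paste0(cur, "\x01", it)
      nid <- get0(key, envir = children, inherits = FALSE)
      if (is.null(nid)) {
        n <- n + 1L
        item[n] <- it
        count[n] <- wj
        parent[n] <- cur
        assign(key, n, envir = children)
        cur <- n
      } else {
        count[nid] <- count[nid] + wj
        cur <- nid
      }
    }
  }
  list(item = item, count = count, parent = parent)
}

#' Derive pairwise association rules from frequent itemsets
#'
#' For every frequent pair \{x, y\} emits both directed rules x -> y and
#' y -> x with `rule_probability` (confidence) equal to
#' support(\{x, y\}) / support(antecedent).
#'
#' @param itemsets Frequent itemsets from [mine_frequent_itemsets()]; must
#'   include all frequent singletons and pairs.
#' @return A tibble with columns `antecedent`, `consequent`, `support`
#'   (pair support) and `rule_probability`, ordered by descending support.
#' @export
derive_pair_rules <- function(itemsets) {
  empty <- tibble::tibble(
    antecedent = character(), consequent = character(),
    support = numeric(), rule_probability = numeric()
  )
  if (nrow(itemsets) == 0) {
    return(empty)
  }
  singles <- itemsets[itemsets$size == 1, ]
  single_supp <- stats::setNames(
    singles$support, vapply(singles$items, identity, character(1))
  )
  pairs <- itemsets[itemsets$size == 2, ]
  if (nrow(pairs) == 0) {
    return(empty)
  }
  x <- vapply(pairs$items, `[`, character(1), 1)
  y <- vapply(pairs$items, `[`, character(1), 2)
  stopifnot(all(c(x, y) %in% names(single_supp)))  # anti-monotonicity
  out <- tibble::tibble(
    antecedent = c(x, y),
    consequent = c(y, x),
    support = rep(pairs$support, 2),
    rule_probability = unname(rep(pairs$support, 2) / single_supp[c(x, y)])
  )
  out <- out[order(-out$support, out$antecedent, out$consequent), ]
  tibble::remove_rownames(out)
}

#' Select quit-lexicon keywords from association rules
#'
#' Lexicon derivation step: among rules whose consequent is the anchor
#' token (default `"vaping"`), keep antecedents whose pair support and rule
#' probability both meet their thresholds (inclusive comparisons), ordered
#' by descending support. With the study thresholds (support 1000,
#' probability 0.30) this yields `"quit"` and `"stop"`, whose variants then
#' form the quit-mention lexicon.
#'
#' @param rules Rule tibble from [derive_pair_rules()].
#' @param anchor Consequent token anchoring the lexicon (default
#'   `"vaping"`).
#' @param min_support Minimum pair support (default 1000).
#' @param min_rule_probability Minimum rule probability (default 0.30);
#'   compared inclusively, with a 1e-12 guard against floating-point
#'   representation of ratio thresholds.
#' @return Character vector of selected antecedent tokens (possibly empty),
#'   by descending support.
#' @export
select_quit_keywords <- function(rules, anchor = "vaping",
                                 min_support = 1000,
                                 min_rule_probability = 0.30) {
  keep <- rules$consequent == anchor &
    rules$support >= min_support &
    rules$rule_probability >= min_rule_probability - 1e-12
  sel <- rules[keep, ]
  sel$antecedent[order(-sel$support)]
}
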