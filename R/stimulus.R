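# -- constants of the experimental design ------------------------------------

WORD_DURATION <- 0.5   # seconds per word
CHUNK_LEN <- 2         # words per chunk
N_CHUNKS <- 12         # chunks per sequence
N_WORDS <- N_CHUNKS * CHUNK_LEN
SEQ_DURATION <- N_WORDS * WORD_DURATION  # 12 s

CONDITIONS <- c("same_category", "different_category")
ORDER_TYPES <- c("alternating", "random")
SUBCATEGORIES <- c(animal = "L", plant = "L",
                   manipulatable = "N", non_manipulatable = "N")

#' Word-onset grid of a sequence
#'
#' Words are presented isochronously at 2 Hz, so onsets fall on a fixed grid
#' of 0, 0.5, ..., 11.5 seconds.
#'
#' @return Numeric vector of 24 onset times in seconds.
#' @export
word_onsets <- function() seq(0, by = WORD_DURATION, length.out = N_WORDS)

#' Build the synthetic word vocabulary
#'
#' Creates the 240-noun pool: two semantic categories (living `L`,
#' nonliving `N`), each split into two subcategories of 60 opaque tokens
#' (animals, plants, manipulatable objects, non-manipulatable objects).
#' Word identities are synthetic labels such as `"animal_017"`; only the
#' category structure matters downstream.
#'
#' @param n_per_subcategory Tokens per subcategory (default 60).
#' @return A data.frame with columns `word_id`, `category` (`"L"`/`"N"`),
#'   `subcategory`, and `duration` (seconds, always 0.5).
#' @export
build_vocabulary <- function(n_per_subcategory = 60) {
  sub <- rep(names(SUBCATEGORIES), each = n_per_subcategory)
  idx <- rep(seq_len(n_per_subcategory), times = length(SUBCATEGORIES))
  data.frame(
    word_id = sprintf("%s_%03d", sub, idx),
    category = unname(SUBCATEGORIES[sub]),
    subcategory = sub,
    duration = WORD_DURATION,
    stringsAsFactors = FALSE
  )
}

new_stim_sequence <- function(categories, condition, order_type,
                              is_outlier = FALSE, word_ids = NULL) {
  stopifnot(length(categories) == N_WORDS, all(categories %in% c("L", "N")))
  structure(
    list(
      categories = categories,
      condition = condition,
      order_type = order_type,
      is_outlier = is_outlier,
      word_ids = word_ids,
      onsets = word_onsets()
    ),
    class = "stim_sequence"
  )
}

#' @export
print.stim_sequence <- function(x, ...) {
  cat(sprintf("<stim_sequence> %s / %s%s\n", x$condition, x$order_type,
              if (x$is_outlier) " [outlier]" else ""))
  cat("  categories:", paste(x$categories, collapse = ""), "\n")
  if (!is.null(x$word_ids)) cat("  words filled:", length(x$word_ids), "\n")
  invisible(x)
}

#' Category pattern of an alternating-order sequence
#'
#' The alternating-order sequences have a fixed structure: a four-word unit
#' repeated six times, `NNLL` under the same-category rule and `NLLN` under
#' the different-category rule. The two patterns differ only by a one-word
#' (0.5 s) time lag.
#'
#' @param condition `"same_category"` or `"different_category"`.
#' @return A [stim_sequence] with categories assigned and no word identities.
#' @export
alternating_pattern <- function(condition = CONDITIONS) {
  condition <- match.arg(condition)
  unit <- if (condition == "same_category") c("N", "N", "L", "L")
          else c("N", "L", "L", "N")
  new_stim_sequence(rep(unit, N_CHUNKS / 2), condition, "alternating")
}

valid_chunk_types <- function(condition) {
  if (condition == "same_category") list(c("L", "L"), c("N", "N"))
  else list(c("N", "L"), c("L", "N"))
}

#' Category pattern of a random-order sequence
#'
#' Each of the 12 chunks is drawn independently and uniformly from the two
#' chunk types valid under `condition` (`LL`/`NN` for same-category,
#' `NL`/`LN` for different-category).
#'
#' @inheritParams alternating_pattern
#' @return A [stim_sequence] with categories assigned.
#' @export
random_pattern <- function(condition = CONDITIONS) {
  condition <- match.arg(condition)
  types <- valid_chunk_types(condition)
  draw <- sample.int(2, N_CHUNKS, replace = TRUE)
  new_stim_sequence(unlist(types[draw]), condition, "random")
}

#' Validity of each chunk under a chunking rule
#'
#' @param sequence A [stim_sequence].
#' @param condition Rule to check against; defaults to the sequence's own.
#' @return Logical vector of length 12, `TRUE` where the chunk is valid.
#' @export
chunk_validity <- function(sequence, condition = sequence$condition) {
  m <- matrix(sequence$categories, nrow = CHUNK_LEN)
  same <- m[1, ] == m[2, ]
  if (condition == "same_category") same else !same
}

#' Fill a category pattern with word identities
#'
#' One living subcategory (animals or plants) and one nonliving subcategory
#' (manipulatable or non-manipulatable) are chosen per sequence; each slot is
#' filled from the chosen 60-word pool with no word repeating within the
#' sequence.
#'
#' @param sequence A [stim_sequence] pattern.
#' @param vocabulary Output of [build_vocabulary()].
#' @return The sequence with `word_ids` assigned.
#' @export
fill_words <- function(sequence, vocabulary) {
  subs <- split(vocabulary$word_id, vocabulary$subcategory)
  living <- sample(c("animal", "plant"), 1)
  nonliving <- sample(c("manipulatable", "non_manipulatable"), 1)
  pools <- list(L = sample(subs[[living]]), N = sample(subs[[nonliving]]))
  n_need <- table(factor(sequence$categories, levels = c("L", "N")))
  if (any(n_need > vapply(pools, length, 1L)[names(n_need)]))
    stop("word pool exhausted")  # impossible for the 60-word design
  ids <- character(N_WORDS)
  used <- c(L = 0L, N = 0L)
  for (i in seq_len(N_WORDS)) {
    cat_i <- sequence$categories[i]
    used[cat_i] <- used[cat_i] + 1L
    ids[i] <- pools[[cat_i]][used[cat_i]]
  }
  sequence$word_ids <- ids
  sequence
}

#' Turn a normal sequence into an outlier sequence
#'
#' A living word in one chunk is swapped with a nonliving word in another
#' chunk such that exactly those two chunks become invalid under the
#' sequence's rule. The swapped pair is drawn uniformly over all eligible
#' (position, position) pairs.
#'
#' @param sequence A non-outlier [stim_sequence] with categories assigned.
#' @return The modified sequence with `is_outlier = TRUE`.
#' @export
make_outlier <- function(sequence) {
  if (isTRUE(sequence$is_outlier)) stop("sequence is already an outlier")
  l_pos <- which(sequence$categories == "L")
  n_pos <- which(sequence$categories == "N")
  chunk_of <- function(i) (i - 1L) %/% CHUNK_LEN + 1L
  pairs <- expand.grid(l = l_pos, n = n_pos)
  pairs <- pairs[chunk_of(pairs$l) != chunk_of(pairs$n), , drop = FALSE]
  # keep swaps that invalidate exactly the two touched chunks
  ok <- vapply(seq_len(nrow(pairs)), function(r) {
    cand <- sequence$categories
    cand[c(pairs$l[r], pairs$n[r])] <- cand[c(pairs$n[r], pairs$l[r])]
    v <- chunk_validity(new_stim_sequence(cand, sequence$condition,
                                          sequence$order_type))
    sum(!v) == 2 &&
      all(which(!v) %in% c(chunk_of(pairs$l[r]), chunk_of(pairs$n[r])))
  }, logical(1))
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) == 0) stop("no eligible swap")
  pick <- pairs[sample.int(nrow(pairs), 1), ]
  sw <- c(pick$l, pick$n)
  sequence$categories[sw] <- sequence$categories[rev(sw)]
  if (!is.null(sequence$word_ids))
    sequence$word_ids[sw] <- sequence$word_ids[rev(sw)]
  sequence$is_outlier <- TRUE
  sequence
}

#' Build a full condition block of 60 sequences
#'
#' 30 alternating-order and 30 random-order sequences; in 8 of each, an
#' outlier swap is applied. All 60 are shuffled into a random presentation
#' order. All randomness consumes the current R RNG stream in a fixed order
#' (alternating fills, random fills, outlier choice and swaps, final
#' shuffle), so a `set.seed()` before the call reproduces the block exactly.
#'
#' @inheritParams alternating_pattern
#' @param vocabulary Output of [build_vocabulary()].
#' @param n_per_order Sequences per order type (default 30).
#' @param n_outliers_per_order Outliers per order type (default 8).
#' @return A list of class `condition_block` with elements `condition`,
#'   `sequences` (list of [stim_sequence]) and `presentation_order`.
#' @export
build_condition_block <- function(condition = CONDITIONS, vocabulary,
                                  n_per_order = 30,
                                  n_outliers_per_order = 8) {
  condition <- match.arg(condition)
  alt <- replicate(n_per_order,
                   fill_words(alternating_pattern(condition), vocabulary),
                   simplify = FALSE)
  rnd <- replicate(n_per_order,
                   fill_words(random_pattern(condition), vocabulary),
                   simplify = FALSE)
  out_alt <- sample.int(n_per_order, n_outliers_per_order)
  out_rnd <- sample.int(n_per_order, n_outliers_per_order)
  alt[out_alt] <- lapply(alt[out_alt], make_outlier)
  rnd[out_rnd] <- lapply(rnd[out_rnd], make_outlier)
  seqs <- c(alt, rnd)
  ord <- sample.int(length(seqs))
  structure(list(condition = condition, sequences = seqs[ord],
                 presentation_order = ord),
            class = "condition_block")
}

#' @export
print.condition_block <- function(x, ...) {
  n_out <- sum(vapply(x$sequences, `[[`, logical(1), "is_outlier"))
  cat(sprintf("<condition_block> %s: %d sequences (%d outliers)\n",
              x$condition, length(x$sequences), n_out))
  invisible(x)
}

#' Event table of a sequence
#'
#' @param sequence A [stim_sequence].
#' @return A data.frame with one row per word: `onset_s`, `word_id`,
#'   `category`, `chunk_index`, `chunk_onset`.
#' @export
sequence_events <- function(sequence) {
  data.frame(
    onset_s = sequence$onsets,
    word_id = if (is.null(sequence$word_ids)) NA_character_
              else sequence$word_ids,
    category = sequence$categories,
    chunk_index = rep(seq_len(N_CHUNKS), each = CHUNK_LEN),
    chunk_onset = rep(c(TRUE, FALSE), N_CHUNKS),
    stringsAsFactors = FALSE
  )
}

#' Serialize sequences to JSON
#'
#' @param sequences A list of [stim_sequence] (or a `condition_block`).
#' @param path Optional output file; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
sequences_to_json <- function(sequences, path = NULL) {
  if (inherits(sequences, "condition_block")) sequences <- sequences$sequences
  recs <- lapply(sequences, function(s) {
    list(condition = s$condition, order_type = s$order_type,
         is_outlier = s$is_outlier,
         categories = paste(s$categories, collapse = ""),
         word_ids = s$word_ids, onsets = s$onsets)
  })
  js <- jsonlite::toJSON(recs, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
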