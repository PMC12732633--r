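# Instrument scoring: SUS, PANAS, BPNS, UEQ-S, MDPQ-16, CARS.
# The item arithmetic follows each instrument's published scoring rule;
# item-to-subscale maps and reversal sets are arguments so population- or
# translation-specific variants are data, not code.

check_items <- function(items, n, lo, hi, instrument) {
  if (length(items) != n)
    stop(instrument, " requires exactly ", n, " items (got ",
         length(items), ")", call. = FALSE)
  if (any(!is.finite(items)) || any(items < lo | items > hi))
    stop(instrument, " items must lie in [", lo, ", ", hi, "]",
         call. = FALSE)
  invisible(items)
}

#' Score the System Usability Scale (SUS)
#'
#' Ten items on a 1-5 Likert scale; odd items contribute value - 1, even
#' items 5 - value, and the sum is scaled by 2.5 to a 0-100 range. Scores
#' of 70 or more are conventionally "acceptable", 80 or more "excellent".
#'
#' @param items Numeric vector of 10 item responses in 1..5.
#' @return SUS score in \[0, 100\].
#' @export
#' @examples
#' score_sus(rep(3, 10))  # 50
score_sus <- function(items) {
  check_items(items, 10, 1, 5, "SUS")
  odd <- items[seq(1, 9, by = 2)]
  even <- items[seq(2, 10, by = 2)]
  2.5 * (sum(odd - 1) + sum(5 - even))
}

#' Score the Positive and Negative Affect Schedule (PANAS)
#'
#' Twenty items on a 1-5 scale; the positive-affect (PA) and
#' negative-affect (NA) subscales are sums of their ten items, each ranging
#' 10-50. The default NA item set is the published one; pass `na_items` for
#' variants.
#'
#' @param items Numeric vector of 20 item responses in 1..5.
#' @param na_items Indices of the negative-affect items.
#' @return List with `pa` and `na` sums.
#' @export
score_panas <- function(items, na_items = c(2, 4, 6, 7, 8, 11, 13, 15, 18, 20)) {
  check_items(items, 20, 1, 5, "PANAS")
  if (length(na_items) != 10 || any(!na_items %in% 1:20))
    stop("na_items must select 10 of the 20 PANAS items", call. = FALSE)
  list(pa = sum(items[-na_items]), na = sum(items[na_items]))
}

#' Score the Basic Psychological Needs Satisfaction scale (BPNS)
#'
#' Twenty-one items on a 1-5 scale across autonomy (7 items), competence
#' (6) and relatedness (8). Reverse-scored items are mapped value -> 6 -
#' value before averaging; each subscale is the mean of its items, in
#' \[1, 5\]. The subscale maps follow the published form; the reversal set
#' defaults to empty and is supplied as data.
#'
#' @param items Numeric vector of 21 item responses in 1..5.
#' @param autonomy_items,competence_items,relatedness_items Item indices
#'   for the three subscales (must partition 1..21 as 7/6/8).
#' @param reverse_items Indices of reverse-scored items.
#' @return List with `autonomy`, `competence`, `relatedness` means.
#' @export
score_bpns <- function(items,
                       autonomy_items = c(1, 4, 8, 11, 14, 17, 20),
                       competence_items = c(3, 5, 10, 13, 15, 19),
                       relatedness_items = c(2, 6, 7, 9, 12, 16, 18, 21),
                       reverse_items = integer(0)) {
  check_items(items, 21, 1, 5, "BPNS")
  if (length(autonomy_items) != 7 || length(competence_items) != 6 ||
      length(relatedness_items) != 8 ||
      !setequal(c(autonomy_items, competence_items, relatedness_items), 1:21))
    stop("BPNS subscales must partition the 21 items as 7/6/8", call. = FALSE)
  scored <- items
  scored[reverse_items] <- 6 - scored[reverse_items]
  list(autonomy = mean(scored[autonomy_items]),
       competence = mean(scored[competence_items]),
       relatedness = mean(scored[relatedness_items]))
}

#' Score the short User Experience Questionnaire (UEQ-S)
#'
#' Eight bipolar items on a 1-7 scale, recoded to -3..+3 (value - 4).
#' Pragmatic quality is the mean of items 1-4, hedonic quality the mean of
#' items 5-8.
#'
#' @param items Numeric vector of 8 item responses in 1..7.
#' @return List with `pragmatic` and `hedonic` means in \[-3, 3\].
#' @export
score_ueq_s <- function(items) {
  check_items(items, 8, 1, 7, "UEQ-S")
  v <- items - 4
  list(pragmatic = mean(v[1:4]), hedonic = mean(v[5:8]))
}

#' Score the screening instruments (MDPQ-16 and CARS)
#'
#' MDPQ-16: 16 items in 1..5 across 8 two-item subscales; the total is the
#' sum of subscale means, implemented as item mean x 8 (range 8-40). CARS:
#' the item mean, fed to [screen_technology_anxiety()].
#'
#' @param mdpq_items Numeric vector of 16 MDPQ-16 responses in 1..5.
#' @param cars_items Numeric vector of CARS responses (default length 19)
#'   in 1..5.
#' @param cars_length Declared CARS form length.
#' @return List with `mdpq_total` and `cars_mean`.
#' @export
score_screening <- function(mdpq_items, cars_items, cars_length = 19) {
  check_items(mdpq_items, 16, 1, 5, "MDPQ-16")
  check_items(cars_items, cars_length, 1, 5, "CARS")
  list(mdpq_total = mean(mdpq_items) * 8, cars_mean = mean(cars_items))
}

INSTRUMENT_SPECS <- list(
  sus = list(n = 10, lo = 1, hi = 5),
  panas = list(n = 20, lo = 1, hi = 5),
  bpns = list(n = 21, lo = 1, hi = 5),
  ueq_s = list(n = 8, lo = 1, hi = 7),
  mdpq16 = list(n = 16, lo = 1, hi = 5),
  cars = list(n = 19, lo = 1, hi = 5)
)

#' Score a table of instrument responses
#'
#' Takes a long response table (one row per participant per administration,
#' columns `participant_id`, `instrument`, `timepoint`, `item_1` ...
#' `item_k`, as read from CSV) and returns one row per administration with
#' the instrument's scores (`score_1`, `score_2`, ... named per
#' instrument).
#'
#' @param responses Data frame of responses.
#' @return Data frame of scores in long form: `participant_id`,
#'   `instrument`, `timepoint`, `scale`, `score`.
#' @export
score_responses <- function(responses) {
  need <- c("participant_id", "instrument", "timepoint")
  if (!all(need %in% names(responses)))
    stop("response table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- list()
  for (i in seq_len(nrow(responses))) {
    row <- responses[i, ]
    inst <- as.character(row$instrument)
    if (!inst %in% names(INSTRUMENT_SPECS))
      stop("unknown instrument: ", inst, call. = FALSE)
    k <- INSTRUMENT_SPECS[[inst]]$n
    cols <- paste0("item_", seq_len(k))
    if (!all(cols %in% names(responses)))
      stop(inst, " requires columns ", cols[1], "..", cols[k], call. = FALSE)
    items <- as.numeric(row[cols])
    if (any(is.na(items)))
      stop("row ", i, ": ", inst, " has missing items", call. = FALSE)
    scores <- switch(inst,
      sus = list(sus = score_sus(items)),
      panas = score_panas(items),
      bpns = score_bpns(items),
      ueq_s = score_ueq_s(items),
      mdpq16 = list(mdpq_total = mean(check_items(items, 16, 1, 5,
                                                  "MDPQ-16")) * 8),
      cars = list(cars_mean = mean(check_items(items, 19, 1, 5, "CARS")))
    )
    out[[i]] <- data.frame(participant_id = row$participant_id,
                           instrument = inst,
                           timepoint = row$timepoint,
                           scale = names(scores),
                           score = unlist(scores, use.names = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read an instrument response CSV
#'
#' @param path CSV with columns `participant_id`, `instrument`,
#'   `timepoint`, `item_1` ... `item_k`.
#' @return Data frame of responses.
#' @export
read_responses <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a score table as CSV
#'
#' @param scores Data frame as returned by [score_responses()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}
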