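# Original Porter (1980) stemming algorithm.
#
# No stemmer is bundled with base R, and the normalization contract fixes the
# stemmer to the classic Porter definition (not Porter2/Snowball), so the five
# steps are implemented literally here. Words shorter than 3 characters are
# returned unchanged, as in the reference implementation.

.p_is_cons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!.p_is_cons(chars, i - 1L))
  }
  TRUE
}

# consonant/vowel form of a word, e.g. "tree" -> "CCVV"
.p_form <- function(word) {
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  if (!length(chars)) return("")
  paste(vapply(seq_along(chars), function(i) {
    if (.p_is_cons(chars, i)) "C" else "V"
  }, character(1)), collapse = "")
}

# the measure m in the C?(VC){m}V? decomposition
.p_measure <- function(word) {
  form <- gsub("C+", "C", gsub("V+", "V", .p_form(word)))
  lengths(regmatches(form, gregexpr("VC", form)))
}

.p_has_vowel <- function(word) {
  grepl("V", .p_form(word), fixed = TRUE)
}

.p_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  a <- substr(word, n - 1L, n - 1L)
  b <- substr(word, n, n)
  a == b && grepl("C$", .p_form(word))
}

# *o condition: stem ends cvc where the final consonant is not w, x or y
.p_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  if (substr(word, n, n) %in% c("w", "x", "y")) return(FALSE)
  grepl("CVC$", .p_form(word))
}

# Apply the first matching (suffix, replacement) rule whose m-condition holds;
# within a step the longest matching suffix decides, as in the original paper.
.p_rules <- function(word, rules, min_m) {
  for (r in rules) {
    suf <- r[[1]]
    if (endsWith(word, suf)) {
      stem <- substr(word, 1L, nchar(word) - nchar(suf))
      if (.p_measure(stem) > min_m) {
        return(paste0(stem, r[[2]]))
      }
      return(word) # longest suffix matched; condition failed -> stop
    }
  }
  word
}

.p_step1a <- function(w) {
  if (endsWith(w, "sses")) return(sub("sses$", "ss", w))
  if (endsWith(w, "ies")) return(sub("ies$", "i", w))
  if (endsWith(w, "ss")) return(w)
  if (endsWith(w, "s")) return(sub("s$", "", w))
  w
}

.p_step1b <- function(w) {
  if (endsWith(w, "eed")) {
    stem <- sub("eed$", "", w)
    if (.p_measure(stem) > 0L) return(paste0(stem, "ee"))
    return(w)
  }
  fixed <- FALSE
  if (endsWith(w, "ed")) {
    stem <- sub("ed$", "", w)
    if (.p_has_vowel(stem)) {
      w <- stem
      fixed <- TRUE
    }
  } else if (endsWith(w, "ing")) {
    stem <- sub("ing$", "", w)
    if (.p_has_vowel(stem)) {
      w <- stem
      fixed <- TRUE
    }
  }
  if (fixed) {
    if (endsWith(w, "at") || endsWith(w, "bl") || endsWith(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.p_double_cons(w) &&
               !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
      w <- substr(w, 1L, nchar(w) - 1L)
    } else if (.p_measure(w) == 1L && .p_cvc(w)) {
      w <- paste0(w, "e")
    }
  }
  w
}

.p_step1c <- function(w) {
  if (endsWith(w, "y") && .p_has_vowel(substr(w, 1L, nchar(w) - 1L))) {
    return(sub("y$", "i", w))
  }
  w
}

.p_step2_rules <- list(
  list("ational", "ate"), list("tional", "tion"), list("enci", "ence"),
  list("anci", "ance"), list("izer", "ize"), list("abli", "able"),
  list("alli", "al"), list("entli", "ent"), list("eli", "e"),
  list("ousli", "ous"), list("ization", "ize"), list("ation", "ate"),
  list("ator", "ate"), list("alism", "al"), list("iveness", "ive"),
  list("fulness", "ful"), list("ousness", "ous"), list("aliti", "al"),
  list("iviti", "ive"), list("biliti", "ble")
)
# longest-suffix-first order within the step
.p_step2_rules <- .p_step2_rules[order(-vapply(.p_step2_rules, function(r) nchar(r[[1]]), 1L))]

.p_step3_rules <- list(
  list("icate", "ic"), list("ative", ""), list("alize", "al"),
  list("iciti", "ic"), list("ical", "ic"), list("ful", ""), list("ness", "")
)
.p_step3_rules <- .p_step3_rules[order(-vapply(.p_step3_rules, function(r) nchar(r[[1]]), 1L))]

.p_step4_sufs <- c("ement", "ance", "ence", "able", "ible", "ment", "ant",
                   "ent", "ism", "ate", "iti", "ous", "ive", "ize", "ion",
                   "al", "er", "ic", "ou")
.p_step4_sufs <- .p_step4_sufs[order(-nchar(.p_step4_sufs))]

.p_step4 <- function(w) {
  for (suf in .p_step4_sufs) {
    if (endsWith(w, suf)) {
      stem <- substr(w, 1L, nchar(w) - nchar(suf))
      if (suf == "ion" && !grepl("[st]$", stem)) return(w)
      if (.p_measure(stem) > 1L) return(stem)
      return(w)
    }
  }
  w
}

.p_step5 <- function(w) {
  if (endsWith(w, "e")) {
    stem <- substr(w, 1L, nchar(w) - 1L)
    m <- .p_measure(stem)
    if (m > 1L || (m == 1L && !.p_cvc(stem))) w <- stem
  }
  if (endsWith(w, "ll") && .p_measure(w) > 1L) {
    w <- substr(w, 1L, nchar(w) - 1L)
  }
  w
}

.porter1 <- function(word) {
  if (nchar(word) < 3L) return(word)
  w <- .p_step1a(word)
  w <- .p_step1b(w)
  w <- .p_step1c(w)
  w <- .p_rules(w, .p_step2_rules, 0L)
  w <- .p_rules(w, .p_step3_rules, 0L)
  w <- .p_step4(w)
  .p_step5(w)
}

#' Stem words with the original Porter algorithm
#'
#' Applies the classic five-step Porter (1980) suffix-stripping algorithm to
#' each element of a character vector. Input is expected to be lower-case
#' ASCII words; other strings are passed through the same rules unchanged in
#' spirit (the algorithm only inspects letters).
#'
#' @param words character vector of lower-case words.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("sequencing", "bacterial", "chemotaxis", "homeostasis"))
#' @export
porter_stem <- function(words) {
  vapply(as.character(words), .porter1, character(1), USE.NAMES = FALSE)
}
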