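# Shared in-code fixtures: a knee/hip osteoarthritis worked example, a
# perinatal-infection grouping exercising the ambiguity rule, and an
# independent brute-force oracle for block expansion.

fig1_lexicon <- function(extra_terms = NULL) {
  concepts <- data.frame(
    cui = c("C0409959", "C0029410", "C0003864"),
    preferred_name = c("Osteoarthritis, Knee", "Osteoarthritis of hip",
                       "Arthritis"),
    semantic_types = c("T047", "T047", "T047"),
    stringsAsFactors = FALSE)
  terms <- data.frame(
    cui = c("C0409959", "C0409959", "C0029410", "C0029410", "C0003864"),
    term = c("Knee Osteoarthritis", "Osteoarthritis, Knee",
             "Hip Osteoarthritis", "Osteoarthritis of hip", "Arthritis"),
    stringsAsFactors = FALSE)
  if (!is.null(extra_terms)) terms <- rbind(terms, extra_terms)
  crosswalk <- data.frame(
    cui = rep(c("C0409959", "C0029410"), each = 2),
    icd10_spec = rep(c("M16", "M16.9"), 2),
    stringsAsFactors = FALSE)
  build_lexicon(concepts, terms, crosswalk = crosswalk)
}

fig1_trial <- function() {
  trial_record("NCT0000001",
               condition = "Knee Osteoarthritis; Hip Osteoarthritis",
               public_title = "Osteoarthritis of hip and knee study",
               scientific_title =
                 "A trial in patients with Knee Osteoarthritis")
}

# Grouping in which the perinatal-infection code P37 is ambiguous: its .0
# extension is tuberculosis, its .3 a neglected tropical disease.
p37_grouping <- function() {
  build_grouping(
    category_id = c("tuberculosis", "neglected_tropical", "neonatal",
                    "neonatal"),
    category_name = c("Tuberculosis", "Neglected tropical diseases",
                      "Neonatal disorders", "Neonatal disorders"),
    residual = c(FALSE, FALSE, FALSE, FALSE),
    icd10_spec = c("P37.0", "P37.3", "P00-P36.9", "P38-P96.9"),
    name = "p37")
}

# Independent oracle: enumerate the full syntactic grid of codes, sort it
# lexicographically by (letter, major, minor with absent first) using
# order() on the separate fields — never via the package's integer sort
# key — and slice between the endpoints.
.oracle_grid <- local({
  grid <- expand.grid(minor = c(-1, 0:9), major = 0:99, letter = LETTERS,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$letter, grid$major, grid$minor), ]
  ifelse(grid$minor < 0,
         sprintf("%s%02d", grid$letter, grid$major),
         sprintf("%s%02d.%d", grid$letter, grid$major, grid$minor))
})

brute_force_expand <- function(start_str, end_str) {
  i <- match(start_str, .oracle_grid)
  j <- match(end_str, .oracle_grid)
  stopifnot(!is.na(i), !is.na(j), i <= j)
  .oracle_grid[i:j]
}

# Random small block within one letter, as canonical strings.
random_block <- function() {
  letter <- sample(LETTERS, 1)
  k <- sort(sample(0:329, 2))  # 30 majors x 11 slots
  to_code <- function(x) {
    major <- x %/% 11; slot <- x %% 11
    if (slot == 0) sprintf("%s%02d", letter, major)
    else sprintf("%s%02d.%d", letter, major, slot - 1)
  }
  c(to_code(k[1]), to_code(k[2]))
}
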