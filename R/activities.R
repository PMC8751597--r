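#' Catalogue of the 33 daily-activity variables
#'
#' The pipeline tracks 33 self-reported daily activities covering cognitively
#' challenging, mild physical, housework, social and leisure domains. Each is
#' an ordinal engagement level coded `0 .. n_levels - 1` ("never" up to
#' "daily"); activities are coded in six or seven ordered categories.
#' The `key` column gives the canonical machine-readable name used as the
#' internal identifier throughout the pipeline (column names in cohort files,
#' row names in p-value matrices); `label` is the human-readable survey name.
#'
#' @return A data.frame with columns `key` (character), `label` (character)
#'   and `n_levels` (integer, 6 or 7), one row per activity, 33 rows.
#' @export
#' @examples
#' cat33 <- activity_catalog()
#' nrow(cat33)
activity_catalog <- function() {
  labels <- c(
    "CARE ADULT",
    "DO ACTIVITIES WITH GRANDCHILDREN",
    "VOLUNTEER YOUTH",
    "CHARITY WORK",
    "EDUCATION",
    "ATTEND SPORTS/SOCIAL/CLUB",
    "ATTEND NON RELIGIOUS ORGS",
    "PRAY PRIVATELY",
    "READ",
    "WATCH TELEVISION",
    "DO WORD GAMES",
    "PLAY CARDS AND GAMES",
    "DO WRITING",
    "USE COMPUTER",
    "MAINTENANCE/GARDENING",
    "BAKE OR COOK",
    "SEW OR KNIT",
    "DO HOBBY",
    "PLAY SPORT/EXERCISE",
    "WALK FOR 20 MINS",
    "PARTICIPATE COMMUNITY ARTS GRP",
    "MEET UP WITH CHILDREN",
    "SPEAK ON PHONE WITH CHILDREN",
    "WRITE OR EMAIL CHILDREN",
    "COMMUNICATE BY SOCIAL MEDIA",
    "MEET UP WITH OTHER FAMILY MEMBERS",
    "SPEAK ON PHONE WITH OTHER FAMILY MEMBERS",
    "WRITE OR EMAIL OTH FAMILY MEMBERS",
    "COMMUNICATE BY SOCIAL MEDIA WITH FAMILY MEMBERS",
    "MEET UP WITH FRIENDS",
    "SPEAK ON PHONE WITH FRIENDS",
    "WRITE OR EMAIL FRIENDS",
    "COMMUNICATE BY SOCIAL MEDIA WITH FRIENDS"
  )
  keys <- c(
    "care_adult", "activities_grandchildren", "volunteer_youth", "charity_work",
    "attend_education", "attend_sports_club", "attend_nonreligious_orgs",
    "pray_privately", "read", "watch_tv", "word_games", "cards_games",
    "writing", "use_computer", "maintenance_gardening", "bake_cook",
    "sew_knit", "hobby", "sport_exercise", "walk_20min", "community_arts",
    "meet_children", "phone_children", "write_children", "social_media",
    "meet_family", "phone_family", "write_family", "social_media_family",
    "meet_friends", "phone_friends", "write_friends", "social_media_friends"
  )
  # social-contact items (22..33) use 6 ordered categories, the rest 7
  n_levels <- c(rep(7L, 21), rep(6L, 12))
  data.frame(key = keys, label = labels, n_levels = n_levels,
             stringsAsFactors = FALSE)
}

#' Age-group labels
#'
#' The five 5-year age bins covering ages 65-89 inclusive, in increasing order.
#'
#' @return Character vector of length 5.
#' @export
age_groups <- function() {
  c("65-69", "70-74", "75-79", "80-84", "85-89")
}

# Non-activity columns every cohort table carries.
cohort_base_columns <- function() {
  c("id", "age_years", "education_years",
    "recall_immediate_w1", "recall_delayed_w1",
    "recall_immediate_w2", "recall_delayed_w2",
    "memory_w1", "memory_w2")
}
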