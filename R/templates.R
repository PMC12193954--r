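# Sentence templates for the synthetic generator. Syntax: fixed text with
# {option|option|...} slots, one option drawn uniformly at render time.
#
# Every PD-related template embeds at least one dictionary term in every slot
# combination (so the lexicon stage has recall 1 on generated positives), and
# the ambiguous negatives embed dictionary terms in clearly non-PD contexts
# (so the classifier's task is non-trivial: both classes contain dictionary
# hits). Plain negatives carry no dictionary vocabulary at all.

TPL_POS_SYMPTOM <- c(
  "my {tremor|trembling|shaking} {got worse|kept acting up|flared badly} {today|tonight|this week|again}",
  "struggling with {stiffness|rigidity|freezing} {this morning|lately|at work|all day}",
  "could not sleep last night, this {tremor|stiffness|cramping} is {brutal|relentless|rough}",
  "hands {shaking|trembling} so badly i dropped my {coffee|keys|phone}",
  "another {fall|stumble} {at home|in the kitchen|on the stairs}, losing my balance scares me",
  "so {tired|exhausted} and {achy|sore} again, my body just feels {slow|heavy|off} lately",
  "my {handwriting|voice|memory} is getting {smaller|softer|worse} and it worries me",
  "{dizzy|lightheaded} spells and {numbness|tingling} in my {hands|feet} again")

TPL_POS_MEDICATION <- c(
  "the {levodopa|sinemet|carbidopa} {kicked in late|wore off early|is helping a lot} {today|this week}",
  "my {neurologist|movement disorder specialist} {adjusted|changed} my {meds|dosage} {today|again|at the clinic}",
  "dbs surgery {consult|evaluation} next {week|month}, nervous but hopeful",
  "side effects from the new {prescription|medication} are {rough|no joke|wearing me down}",
  "waiting at the {neurology|movement disorder} clinic for my {appointment|checkup}",
  "started {ropinirole|amantadine|rasagiline} this week, fingers crossed it helps the {tremor|stiffness}")

TPL_POS_ADVOCACY <- c(
  "join our {team fox|moving day} {walk|fundraiser} for {parkinsons|parkinson research} {this saturday|next month}",
  "our {support group|awareness walk} meets {tonight|saturday}, newcomers welcome",
  "please donate to the {parkinsons foundation|fox foundation} {today|this month|if you can}",
  "proud to volunteer at the {moving day|awareness month} event for parkinsons {again|this year}",
  "signed up for a {clinical trial|research study} on parkinsons, wish me luck")

TPL_POS_EXERCISE <- c(
  "{rock steady boxing|tai chi|yoga} class for {parkinsons|my pd} {tonight|was great|tomorrow}",
  "{treadmill|cycling|stretching} {session|workout} done, keeps the {stiffness|tremor} {manageable|at bay}",
  "{boxing|spin class|pilates} with my parkinsons {group|friends} {this morning|tonight}",
  "daily {walking|stretching} routine helps my {balance|rigidity|slowness} so much")

TPL_NEG_AMBIG <- c(
  "i {fell|tripped} head over heels in love with this {song|show|recipe}",
  "dead {tired|exhausted} after the {long drive|double shift}, pizza and couch time",
  "the {baby|puppy} finally {slept|walked} through the {night|evening}",
  "{shaking|shaky} my head at this {weather|traffic|nonsense}",
  "no pain no gain, {gym|spin class|workout} {crushed|done and dusted}",
  "work life balance is a {myth|joke}, am i right",
  "that {concert|summer trip} is a memory i will treasure {forever|always}",
  "{walked|hiked} the {beach|trail} with the {dog|kids} all morning",
  "my fantasy {football|baseball} team is falling apart {again|fast}",
  "{yoga|swimming} at the {lake|gym} then brunch, perfect {saturday|sunday}",
  "this {cold|headache} has me {exhausted|sleeping} all weekend",
  "the {stock market|bracket} is shaking everyone up {today|this week}")

TPL_NEG_PLAIN <- c(
  "happy birthday to my {wonderful|amazing|favorite} {sister|brother|friend|cousin}",
  "great {dinner|evening|afternoon} with {friends|family|neighbors} at the {lake|new place}",
  "go {tigers|eagles|braves}, what a {game|match|finish}",
  "beautiful {sunset|morning|view} here in {georgia|florida|the mountains}",
  "cannot believe it is already {march|july|october}",
  "recipe of the day, {lasagna|banana bread|gumbo} turned out {perfect|amazing}",
  "the {kids|grandkids} {concert|recital|play} was {adorable|wonderful}",
  "traffic on the {highway|interstate} was unreal {today|this evening}",
  "reading a {fantastic|gripping} {novel|mystery} this {weekend|week}",
  "coffee with {an old friend|the neighbors|my book club} this morning",
  "new {curtains|garden beds|bird feeder} finished, very pleased",
  "congratulations to {my niece|our neighbor|the graduates} on the big {day|news}")

# Genuinely ambiguous sentences used by BOTH classes: a person with PD posting
# about a fall or a bad night is indistinguishable, on surface features, from
# anyone else doing the same. These bound the achievable recall away from 1,
# the way keyword ambiguity does in real annotated corpora.
TPL_SHARED_AMBIG <- c(
  "rough night, could not sleep {at all|a wink}",
  "took a {hard|nasty} fall {today|on the ice|this morning}",
  "my hands are so {shaky|stiff} this {morning|evening}",
  "feeling {slow|tired} {all week|again|lately}",
  "so {stiff|sore} after that long {drive|flight}",
  "dropped my {coffee|drink} everywhere {again|this morning}",
  "another {sleepless|restless} night {ugh|again}",
  "legs {cramping|aching} {again|all night}")

MOJIBAKE_SUFFIXES <- c(" — what a day", " — so it goes", " … oh well",
                       " – feeling it")

FILLER_WORDS <- c("honestly", "truly", "really", "indeed", "folks", "yall",
                  "seriously", "though", "anyway", "right")

# Parse "{a|b}" slots once; render many instances vectorized per template.
parse_template <- function(tpl) {
  m <- gregexpr("\\{[^}]*\\}", tpl)[[1]]
  if (m[1] == -1L) return(list(parts = tpl, slots = list()))
  slots <- regmatches(tpl, gregexpr("\\{[^}]*\\}", tpl))[[1]]
  slots <- lapply(slots, function(s) strsplit(substr(s, 2, nchar(s) - 1), "|", fixed = TRUE)[[1]])
  parts <- strsplit(gsub("\\{[^}]*\\}", "\r", tpl), "\r", fixed = TRUE)[[1]]
  if (length(parts) == length(slots)) parts <- c(parts, "")
  list(parts = parts, slots = slots)
}

# Render n instances of one parsed template.
render_template <- function(parsed, n) {
  if (!length(parsed$slots)) return(rep(parsed$parts, n))
  out <- rep(parsed$parts[1], n)
  for (j in seq_along(parsed$slots)) {
    out <- paste0(out, sample(parsed$slots[[j]], n, replace = TRUE),
                  parsed$parts[j + 1])
  }
  out
}

# Render n texts drawn from a template pool (uniform over templates).
render_pool <- function(pool, n) {
  if (n == 0L) return(character(0))
  ids <- sample.int(length(pool), n, replace = TRUE)
  out <- character(n)
  for (k in unique(ids)) {
    sel <- ids == k
    out[sel] <- render_template(parse_template(pool[k]), sum(sel))
  }
  out
}
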