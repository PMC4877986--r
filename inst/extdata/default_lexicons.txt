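[jargon_terms]
outcome
literature
case series
efficacy
effect size

[ambiguous_terms]
local
blinding
control
practice

[database_names]
MEDLINE
EMBASE
CENTRAL
CINAHL
PsycINFO
PubMed
Scopus
LILACS
AMED

[stat_patterns]
odds_ratio = (?:(?i:\bodds ratios?\b)|\bOR\b)[^.;]{0,20}?-?\d
risk_ratio = (?:(?i:\brisk ratios?\b)|\bRR\b)[^.;]{0,20}?-?\d
hazard_ratio = (?:(?i:\bhazard ratios?\b)|\bHR\b)[^.;]{0,20}?-?\d
smd = (?:(?i:\bstandardi[sz]ed mean differences?\b)|\bSMD\b)[^.;]{0,20}?-?\d
mean_difference = \bMD\b[^.;]{0,20}?-?\d
ci = (?:\b(?:90|95|99)\s?%\s?(?:CI\b|(?i:confidence interval))|(?i:\bconfidence intervals?\b))

[quality_phrases]
quality of (the )?(evidence|included studies|studies|trials)
certainty of (the )?evidence
risk of bias
\b(very low|low|moderate|high)[- ]quality\b
methodological quality

[recommended_headings]
Review question
Background
Study characteristics
Key results
Quality of evidence

[heading_variants]
review question = Review question
review questions = Review question
background = Background
study characteristics = Study characteristics
key results = Key results
quality of evidence = Quality of evidence
quality of the evidence = Quality of evidence

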