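# Placeholder seed-word lists for the five original RDoC domains, in the
# format read by readDomainSeeds(): domain<TAB>seed1 seed2 ...
# These generic English terms are a starting point only; replace them with
# a curated seed list matched to your embedding vocabulary.
negative_valence	fear anxiety threat loss sadness distress
positive_valence	reward motivation pleasure approach satisfaction
cognitive_systems	attention memory perception language cognition
social_processes	attachment communication social affiliation perception
arousal_regulatory	arousal sleep wakefulness circadian regulation
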