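pattern_id	priority	type	connector	enabled	template
1	1	protein_then_mutation	^\s*[-–]\s*$	TRUE	<protein> - <mutation>
2	2	mutation_then_protein	^\s+(of|in)\s+(the\s+)?$	TRUE	<mutation> of|in <protein>
3	3	mutation_then_protein	^\s+for\s+(the\s+)?$	TRUE	<mutation> for the <protein>
4	4	enumeration_then_protein	^\s+(for|of|in)\s+(the\s+)?$	TRUE	mutations <mutation A>, <mutation B> and <mutation C> for <protein>
5	5	proximity	5	FALSE	nearest <protein> within 5 tokens
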