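type	template
Add	{CM} ({mass} g, {molar} mmol) was added to the {CM2}.
ApparatusAction	A {n} ml round-bottom flask was sealed with a septum.
Concentrate	The filtrate was concentrated under reduced pressure.
Cool	The reaction was then cooled to rt.
Degass	The solution was purged with {GAS} for {time} min.
Dissolve	{CM} was dissolved in {CM2}.
Dry	The yellow product was dried under vacuum.
Extract	The products were extracted with {CM} ({n} × {vol} ml).
Filter	The solution was filtered through a short silica gel column.
Heat	The mixture was heated under reflux for {time} h.
Partition	The reaction mixture was partitioned between {CM} ({vol} ml) and {CM2} ({vol2} ml).
Precipitate	Precipitating in {CM}.
Purify	The mixture was purified by column chromatography.
Quench	The reaction was quenched with {CM}.
Recover	The precipitate was recovered by filtration.
Remove	The solvent was removed under reduced pressure.
Stir	The reaction mixture was stirred at room temperature for {time} h.
Synthesize	Synthesis of {CM} by condensation.
Wait	The mixture was left for {time} h under stirring.
Wash	The resin was washed with {CM}.
Yield	Chromatography afforded the title compound **{ref}** ({mass} g, {percent}%) as a colourless oil.
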