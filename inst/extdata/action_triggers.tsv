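type	tag	forms	nominal
Add	VB-ADD	add|adds|added|adding
ApparatusAction	VB-APPARATUS	seal|seals|sealed|sealing|fit|fits|fitted|fitting|equip|equips|equipped|equipping|connect|connects|connected|connecting
Concentrate	VB-CONCENTRATE	concentrate|concentrates|concentrated|concentrating|evaporate|evaporates|evaporated|evaporating
Cool	VB-COOL	cool|cools|cooled|cooling|chill|chills|chilled|chilling
Degass	VB-DEGASS	purge|purges|purged|purging|degas|degass|degassed|degassing|bubble|bubbles|bubbled|bubbling
Dissolve	VB-DISSOLVE	dissolve|dissolves|dissolved|dissolving
Dry	VB-DRY	dry|dries|dried|drying
Extract	VB-EXTRACT	extract|extracted|extracting
Filter	VB-FILTER	filter|filters|filtered|filtering
Heat	VB-HEAT	heat|heats|heated|heating|reflux|refluxed|refluxing|warm|warms|warmed|warming
Partition	VB-PARTITION	partition|partitions|partitioned|partitioning
Precipitate	VB-PRECIPITATE	precipitated|precipitating|precipitates
Purify	VB-PURIFY	purify|purifies|purified|purifying|recrystallise|recrystallised|recrystallize|recrystallized
Quench	VB-QUENCH	quench|quenches|quenched|quenching
Recover	VB-RECOVER	recover|recovers|recovered|recovering
Remove	VB-REMOVE	remove|removes|removed|removing
Stir	VB-STIR	stir|stirs|stirred|stirring
Synthesize	VB-SYNTHESIZE	synthesise|synthesised|synthesize|synthesized|synthesising|synthesizing	synthesis|preparation
Wait	VB-WAIT	wait|waits|waited|waiting|left|stood|stand|stands|standing
Wash	VB-WASH	wash|washes|washed|washing
Yield	VB-YIELD	afford|affords|afforded|affording|yield|yields|yielded|yielding|give|gives|gave|given|giving|obtain|obtains|obtained|obtaining
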