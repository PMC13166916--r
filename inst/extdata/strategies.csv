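landcover,limited,strategy
forest,soil_c+net_uptake,"Retain leaf litter and deadwood at edges; establish shade-tolerant native understory shrubs and groundcovers to shade soil, sustain moisture and slow decomposition"
forest,vegetation_c+soil_c,"Enrichment planting with native canopy and midstory species; retain litter layer to rebuild organic inputs"
forest,vegetation_c+net_uptake,"Thin suppressed stems and underplant vigorous native saplings to restore canopy productivity"
forest,all,"Edge-focused restoration: avoid intensive leaf litter removal, plant shade-tolerant understory, and buffer the edge against disturbance"
forest,any,"Protect existing stocks; minimise disturbance and litter removal"
agricultural,vegetation_c+soil_c,"Conservation agriculture: retain crop residues as surface mulch, shift toward no-till or strip-till, and integrate biochar and compost applications"
agricultural,soil_c+net_uptake,"Retain residues, add organic amendments, and introduce winter cover crops to extend carbon uptake"
agricultural,vegetation_c+net_uptake,"Agroforestry elements (hedgerows, boundary trees) and cover cropping to raise standing biomass and uptake"
agricultural,all,"Full conservation-agriculture bundle: residue retention, reduced tillage intensity, cover crops, biochar and compost"
agricultural,any,"Reduce tillage intensity and retain crop residues"
park,soil_c+net_uptake,"Alleviate compaction with periodic aeration combined with organic mulch or compost amendments; preserve litter layers"
park,vegetation_c+soil_c,"Multilayered plantings with deep-rooted shrub species over amended, decompacted soil"
park,vegetation_c+net_uptake,"Densify plantings with multilayer structure; favour vigorous deep-rooted species"
park,all,"Integrated park soil and vegetation programme: aeration, organic amendments, litter preservation, multilayer planting, and connectivity via green corridors and pocket parks"
park,any,"Preserve litter layers and avoid soil compaction"
roadside,soil_c+net_uptake,"Mitigate soil sealing and compaction by enlarging planting strips and using permeable surfaces; add organic amendments"
roadside,vegetation_c+soil_c,"Design multilayered roadside plantings with drought-tolerant understory species over decompacted, amended planting strips"
roadside,vegetation_c+net_uptake,"Multilayered drought-tolerant plantings and pruning regimes that maintain canopy vigour while avoiding excessive biomass removal"
roadside,all,"Integrated roadside bundle: multilayered drought-tolerant plantings, moderated pruning, enlarged permeable planting strips, and soil decompaction"
roadside,any,"Maintain canopy vigour; avoid excessive pruning and soil sealing"
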