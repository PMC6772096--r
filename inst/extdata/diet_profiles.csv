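species,prop_breeding,prop_nonbreeding,prop_chick,override_group
chaffinch,44,25,,
corn_bunting,44,75,16,
goldfinch,0,0,,
greenfinch,16,11,21,
grey_partridge,12,28,21,
house_sparrow,37,23,24,
jackdaw,,,11,medium
kestrel,0,0,0,
lapwing,0,0,0,
linnet,0,0,71,
red_legged_partridge,,44,29,
reed_bunting,0,69,0,
rook,38,58,34,
skylark,22,36,2,
starling,0,51,0,medium
stock_dove,61,22,5,
tree_sparrow,22,36,15,
turtle_dove,99,,70,
whitethroat,0,0,0,
woodpigeon,50,45,47,
yellow_wagtail,0,0,0,
yellowhammer,92,32,4,
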