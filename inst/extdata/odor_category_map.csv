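category,keyword
green,green
green,grassy
green,lettuce
floral,floral
floral,rose
floral,roses
floral,violet
floral,hyacinth
floral,gardenia
floral,lilac
fruity,fruity
fruity,apple
fruity,citrus
fruity,pears
fruity,litchi
fruity,grape
fruity,cantaloupe
fruity,oranges
vegetable,vegetable
vegetable,mushroom
vegetable,earthy
vegetable,tomato vine
fatty,fatty
fatty,deep-fried
fatty,wax
fatty,grease
fatty,soap
fatty,soapy
irritant,smoky
irritant,herbal
irritant,herbs
irritant,spicy
irritant,metallic
irritant,wintergreen
irritant,cinnamon
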