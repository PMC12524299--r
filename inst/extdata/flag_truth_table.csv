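condition_id,aux_config,flags
plain,none,
sesame,none,
peanut,none,
strawberry,none,
plain_peanut,none,
sesame_peanut,none,
plain_strawberry,none,
sesame_strawberry,none,
plain,combo,combination=0
sesame,combo,combination=0
peanut,combo,combination=0
strawberry,combo,combination=0
plain_peanut,combo,combination=1
sesame_peanut,combo,combination=1
plain_strawberry,combo,combination=1
sesame_strawberry,combo,combination=1
plain,cracker_spread,cracker=1;spread=0
sesame,cracker_spread,cracker=1;spread=0
peanut,cracker_spread,cracker=0;spread=1
strawberry,cracker_spread,cracker=0;spread=1
plain_peanut,cracker_spread,cracker=1;spread=1
sesame_peanut,cracker_spread,cracker=1;spread=1
plain_strawberry,cracker_spread,cracker=1;spread=1
sesame_strawberry,cracker_spread,cracker=1;spread=1
plain,exclusive3,cracker=1;spread=0;combination=0
sesame,exclusive3,cracker=1;spread=0;combination=0
peanut,exclusive3,cracker=0;spread=1;combination=0
strawberry,exclusive3,cracker=0;spread=1;combination=0
plain_peanut,exclusive3,cracker=0;spread=0;combination=1
sesame_peanut,exclusive3,cracker=0;spread=0;combination=1
plain_strawberry,exclusive3,cracker=0;spread=0;combination=1
sesame_strawberry,exclusive3,cracker=0;spread=0;combination=1
plain,brand,premium=1;sesame=0;peanut=0;strawberry=0
sesame,brand,premium=0;sesame=1;peanut=0;strawberry=0
peanut,brand,premium=0;sesame=0;peanut=1;strawberry=0
strawberry,brand,premium=0;sesame=0;peanut=0;strawberry=1
plain_peanut,brand,premium=1;sesame=0;peanut=1;strawberry=0
sesame_peanut,brand,premium=0;sesame=1;peanut=1;strawberry=0
plain_strawberry,brand,premium=1;sesame=0;peanut=0;strawberry=1
sesame_strawberry,brand,premium=0;sesame=1;peanut=0;strawberry=1
plain,brand_combo,premium=1;sesame=0;peanut=0;strawberry=0;combination=0
sesame,brand_combo,premium=0;sesame=1;peanut=0;strawberry=0;combination=0
peanut,brand_combo,premium=0;sesame=0;peanut=1;strawberry=0;combination=0
strawberry,brand_combo,premium=0;sesame=0;peanut=0;strawberry=1;combination=0
plain_peanut,brand_combo,premium=1;sesame=0;peanut=1;strawberry=0;combination=1
sesame_peanut,brand_combo,premium=0;sesame=1;peanut=1;strawberry=0;combination=1
plain_strawberry,brand_combo,premium=1;sesame=0;peanut=0;strawberry=1;combination=1
sesame_strawberry,brand_combo,premium=0;sesame=1;peanut=0;strawberry=1;combination=1
plain,brand_cs,premium=1;sesame=0;peanut=0;strawberry=0;cracker=1;spread=0
sesame,brand_cs,premium=0;sesame=1;peanut=0;strawberry=0;cracker=1;spread=0
peanut,brand_cs,premium=0;sesame=0;peanut=1;strawberry=0;cracker=0;spread=1
strawberry,brand_cs,premium=0;sesame=0;peanut=0;strawberry=1;cracker=0;spread=1
plain_peanut,brand_cs,premium=1;sesame=0;peanut=1;strawberry=0;cracker=1;spread=1
sesame_peanut,brand_cs,premium=0;sesame=1;peanut=1;strawberry=0;cracker=1;spread=1
plain_strawberry,brand_cs,premium=1;sesame=0;peanut=0;strawberry=1;cracker=1;spread=1
sesame_strawberry,brand_cs,premium=0;sesame=1;peanut=0;strawberry=1;cracker=1;spread=1
plain,brand_all,premium=1;sesame=0;peanut=0;strawberry=0;cracker=1;spread=0;combination=0
sesame,brand_all,premium=0;sesame=1;peanut=0;strawberry=0;cracker=1;spread=0;combination=0
peanut,brand_all,premium=0;sesame=0;peanut=1;strawberry=0;cracker=0;spread=1;combination=0
strawberry,brand_all,premium=0;sesame=0;peanut=0;strawberry=1;cracker=0;spread=1;combination=0
plain_peanut,brand_all,premium=1;sesame=0;peanut=1;strawberry=0;cracker=0;spread=0;combination=1
sesame_peanut,brand_all,premium=0;sesame=1;peanut=1;strawberry=0;cracker=0;spread=0;combination=1
plain_strawberry,brand_all,premium=1;sesame=0;peanut=0;strawberry=1;cracker=0;spread=0;combination=1
sesame_strawberry,brand_all,premium=0;sesame=1;peanut=0;strawberry=1;cracker=0;spread=0;combination=1
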