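{"newspaper":"peoples_daily","year":2020,"month":1,"text":"国务院发布卫生领域新规，市场走向不确定","id":"a000001"}
{"newspaper":"peoples_daily","year":2020,"month":1,"text":"本地新闻：社区活动丰富多彩","id":"a000002"}
{"newspaper":"peoples_daily","year":2020,"month":2,"text":"医保政策调整，患者负担波动引发讨论","id":"a000003"}
{"newspaper":"peoples_daily","year":2020,"month":2,"text":"天气晴好，适合出行","id":"a000004"}
{"newspaper":"peoples_daily","year":2020,"month":3,"text":"卫生系统监管趋严，行业前景不明朗","id":"a000005"}
{"newspaper":"peoples_daily","year":2020,"month":3,"text":"教育话题：新学期开学","id":"a000006"}
{"newspaper":"nanfang_daily","year":2020,"month":1,"text":"医药行业受政府整治影响，利润流失明显","id":"a000007"}
{"newspaper":"nanfang_daily","year":2020,"month":1,"text":"体育赛事回顾","id":"a000008"}
{"newspaper":"nanfang_daily","year":2020,"month":2,"text":"卫生预算由人大审议，未来走势难以预测","id":"a000009"}
{"newspaper":"nanfang_daily","year":2020,"month":2,"text":"文化专栏：书评","id":"a000010"}
{"newspaper":"nanfang_daily","year":2020,"month":3,"text":"医改推进中的不稳因素受到关注，卫生支出承压","id":"a000011"}
{"newspaper":"nanfang_daily","year":2020,"month":3,"text":"旅游指南：周末好去处","id":"a000012"}
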